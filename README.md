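# sporeflux

Quantification of dormant thermophilic fermentative endospores (TFEs) in
marine sediment and seawater, and budgeting of their deposition and decay
during burial.

Cold seabeds accumulate heat-resistant endospores of thermophilic bacteria
that cannot grow there; they arrive suspended in seawater and are buried
with settling particles. Incubating pasteurized sediment anaerobically at
50 °C wakes these spores up, and the signals of their germination and
growth — fermentation products, dilution-culture positivity, released
dipicolinic acid (DPA) — each carry a spore count. `sporeflux` implements
the full quantitative chain for researchers working on microbial dispersal
and the sediment "spore seed bank":

* **Growth-kinetics enumeration.** VFA-carbon (molar volatile fatty acid
  concentrations weighted by carbon atoms per molecule) accumulates as
  `C(t) = C_bg + (qN₀/μ)(e^{μ(t−t_lag)} − 1)` once germinated spores start
  dividing. An exponential anchored at the pre-onset baseline mean is
  fitted to the accumulation phase; its initial derivative `r_on = k·C0`
  divided by the FISH-calibrated cell-specific rate `q` gives the number
  of germinated endospores.
* **Maximum-likelihood MPN.** Tubes at sample volume `v` are positive with
  probability `1 − e^{−Dv}` (Poisson seeding); the binomial likelihood
  across dilution levels is maximized for the density `D`, with 95%
  profile-likelihood confidence limits (log-likelihood drop of
  χ²₁/2 = 1.92). Tubes are scored positive when acetate strictly exceeds
  0.60 mM.
* **DPA standard addition.** Sample concentration from the x-intercept of
  signal vs added DPA; spore equivalents via 2.24 × 10⁻¹⁶ mol DPA per
  spore.
* **Burial decay and deposition budget.** First-order decay of abundance
  with sediment age (log-linear OLS → half-life), deposition flux
  `(n_TFE + n_SRB) · ω · 10⁴` spores m⁻² yr⁻¹ with an optional
  accumulation-decay correction `λT/(1 − e^{−λT})`, and the per-mL
  seawater supply required to sustain that flux.
* **Seeded synthetic-data generators** for every input table (time
  courses, MPN tube tables, depth profiles, standard-addition series), so
  the whole pipeline is testable without external data.

## Worked example

Simulate a surface-sediment slurry incubation under the default study
conditions (2 × 10⁶ germinated cells mL⁻¹ slurry, 640 fmol C cell⁻¹ h⁻¹,
3.5 h lag, 22 min doubling, 5% measurement noise) and enumerate:

```r
library(sporeflux)

sc <- slurry_scenario(seed = 42)
tc <- simulate_slurry_timecourse(sc, seq(0, 5, by = 0.25))

detect_onset(tc, baseline_window = c(0, 3.5))
#> [1] 3.5

fit <- fit_exponential(tc, fit_window = c(3.5, 5), baseline_window = c(0, 3.5))
fit
#> Anchored exponential growth fit
#>   window        : 3.50-5.00 h
#>   C0 (anchor)   : 0.6909 mM C
#>   k             : 1.845 /h
#>   doubling time : 22.5 min
#>   initial rate  : 1.275 mM C/h at t = 3.50 h
#>   rmse (log)    : 0.0634

abundance_from_rate(fit$r_on, q = 6.4e-13, slurry = slurry_spec(1, 2))
#> Endospore abundance (vfa_rate)
#>   slurry   : 1.99e+06 cells/mL
#>   sediment : 5.97e+06 cells/mL
```

Production takes off at 3.5 h; the fitted 22.5-min doubling time and
1.275 mM C h⁻¹ initial rate recover the generating scenario, and dividing
by the cell-specific rate yields ~2 × 10⁶ germinated endospores per mL
slurry — ~6 × 10⁶ per mL sediment after the 1:2 slurry correction.

MPN from a tube pattern (3 positives of 3 at 0.1 mL of sample per tube,
none at 0.01 or 0.001 mL):

```r
mpn_ml(mpn_design(c(0.1, 0.01, 0.001), tubes = 3, positives = c(3, 0, 0)))
#> Maximum-likelihood MPN estimate
#>   density : 23 /mL (ok)
#>   95% CI  : 4.92 - 90.8 /mL
```

Decay with burial and the deposition budget:

```r
fit_decay(simulate_depth_profile(profile_scenario(seed = 42)))
#> First-order burial decay fit
#>   n0        : 5.84e+04 /mL at age 0
#>   lambda    : 0.001982 /yr
#>   half-life : 350 yr (R^2 = 0.949, n = 8)

p <- budget_params()  # 0.09 cm/yr, 1e4 SRB/mL, 15 m depth, 12 d residence
deposition_flux(6e6, p, decay_corrected = TRUE)
#> [1] 5962271893
seawater_supply(deposition_flux(6e6, p), p)
#> [1] 11.85534
```

Roughly 6 × 10⁹ thermophilic endospores are deposited per m² per year,
which requires the water passing through the bay to deliver about 12
endospores per mL.

`run_quantification()` wires all stages into one report, and
`inst/cli/sporeflux.R` exposes `simulate` and `quantify` subcommands for
shell use. See the vignette (`vignettes/endospore-enumeration.Rmd`) for
the models, assumptions and design choices.

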