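#' Slurry incubation scenario for the synthetic time-course generator
#'
#' Describes a pasteurized sediment-slurry incubation in which a germinated
#' endospore population grows exponentially after a lag and excretes
#' VFA-carbon, while dipicolinic acid (DPA) is released in two phases: an
#' instantaneous fraction during pasteurization and a saturating release
#' afterwards.
#'
#' The default scenario reproduces the surface-sediment study conditions:
#' 2e6 germinated cells per mL slurry, cell-specific VFA-carbon production of
#' 640 fmol C per cell per h, onset of detectable production at 3.5 h, and a
#' 22-min doubling time. The default baseline `C_bg` is set to
#' `q * N0 / mu` (in mM) so that the lag-then-exponential accumulation curve
#' is exactly a single exponential anchored at the baseline, which is the
#' regime the growth-kinetics fit assumes.
#'
#' @param N0 initial germinated-population density, cells per mL slurry.
#' @param q cell-specific VFA-carbon production rate, mol C per cell per h.
#' @param t_lag onset of detectable production, h.
#' @param mu specific growth rate, per h. Default `log(2) / (22/60)`
#'   (22-min doubling).
#' @param C_bg baseline VFA-carbon concentration, mM C. Default `q*N0/mu`
#'   converted to mM.
#' @param vfa_split named fractions of VFA-carbon assigned to each VFA
#'   species; must sum to 1. Acetate dominates by default, as observed in
#'   slurry incubations.
#' @param dpa_total releasable DPA pool, nM. The default (582.4 nM) is the
#'   pool implied by 2.6e6 spores per mL at 2.24e-16 mol DPA per spore — a
#'   derived value, since measured DPA magnitudes are not tabulated.
#' @param f_past fraction of the DPA pool released during pasteurization
#'   (before time zero), in `[0, 1]`.
#' @param tau_dpa saturation time constant of post-pasteurization DPA
#'   release, h.
#' @param noise_cv relative (multiplicative) measurement noise on every
#'   analyte; 0 disables noise.
#' @param seed integer seed; identical scenarios with identical seeds give
#'   bit-identical simulated tables.
#' @return an object of class `slurry_scenario`.
#' @seealso [simulate_slurry_timecourse()]
#' @export
slurry_scenario <- function(N0 = 2e6,
                            q = 6.4e-13,
                            t_lag = 3.5,
                            mu = log(2) / (22 / 60),
                            C_bg = mol_per_ml_to_mM(q * N0 / mu),
                            vfa_split = c(acetate = 0.80, propionate = 0.09,
                                          butyrate = 0.06, formate = 0.05),
                            dpa_total = 2.6e6 * 2.24e-16 / nM_to_mol_per_ml(1),
                            f_past = 0.7,
                            tau_dpa = 0.15,
                            noise_cv = 0.05,
                            seed = 1L) {
  check_that(is.numeric(N0) && N0 >= 0, "N0", "must be >= 0")
  check_that(is.numeric(q) && q >= 0, "q", "must be >= 0")
  check_that(is.numeric(t_lag) && t_lag >= 0, "t_lag", "must be >= 0")
  check_that(is.numeric(mu) && mu >= 0, "mu", "must be >= 0")
  check_that(is.numeric(C_bg) && C_bg >= 0, "C_bg", "must be >= 0")
  check_that(is.numeric(vfa_split) && !is.null(names(vfa_split)) &&
               all(vfa_split >= 0), "vfa_split",
             "must be a named vector of non-negative fractions")
  check_that(abs(sum(vfa_split) - 1) < 1e-9, "vfa_split",
             "fractions must sum to 1")
  check_that(all(names(vfa_split) %in% names(vfa_carbon_counts())),
             "vfa_split", "species must be registered VFAs")
  check_that(is.numeric(dpa_total) && dpa_total >= 0, "dpa_total", "must be >= 0")
  check_that(is.numeric(f_past) && f_past >= 0 && f_past <= 1, "f_past",
             "must be in [0, 1]")
  check_that(is.numeric(tau_dpa) && tau_dpa > 0, "tau_dpa", "must be > 0")
  check_that(is.numeric(noise_cv) && noise_cv >= 0, "noise_cv", "must be >= 0")
  structure(
    list(N0 = N0, q = q, t_lag = t_lag, mu = mu, C_bg = C_bg,
         vfa_split = vfa_split, dpa_total = dpa_total, f_past = f_past,
         tau_dpa = tau_dpa, noise_cv = noise_cv, seed = as.integer(seed)),
    class = "slurry_scenario"
  )
}

#' MPN dilution-series scenario for the synthetic tube generator
#'
#' Describes a replicated serial-dilution cultivation assay: each tube at
#' dilution level i receives a Poisson-distributed number of viable spores
#' with mean `true_density * volumes[i]`; a tube turns growth-positive if at
#' least one seeded spore initiates growth (each independently with
#' probability `p_detect`). Grown tubes acquire a high acetate signal, blanks
#' a low one.
#'
#' Default volumes follow a ten-fold series in which the 10^-n tube contains
#' `10^(1-n)` mL of original sample (1 mL inoculum carried through 9 mL
#' blanks), spanning 10^-1 to 10^-7.
#'
#' @param true_density viable culturable spores per mL of original sample.
#' @param volumes per-tube volumes of original sample (mL), one per dilution
#'   level, strictly decreasing.
#' @param replicates tubes per dilution level.
#' @param p_detect probability that a seeded spore produces growth, in (0, 1].
#' @param acetate_pos_mean,acetate_neg_mean mean acetate signal (mM) of grown
#'   and blank tubes. Grown tubes get 10% CV noise, blanks 50% CV, both
#'   truncated at 0.
#' @param seed integer seed.
#' @return an object of class `mpn_scenario`.
#' @seealso [simulate_mpn_tubes()], [mpn_ml()]
#' @export
mpn_scenario <- function(true_density = 4.3e4,
                         volumes = 10^(1 - (1:7)),
                         replicates = 3L,
                         p_detect = 1,
                         acetate_pos_mean = 2.0,
                         acetate_neg_mean = 0.10,
                         seed = 1L) {
  check_that(is.numeric(true_density) && true_density >= 0, "true_density",
             "must be >= 0")
  check_that(is.numeric(volumes) && length(volumes) >= 1 && all(volumes > 0),
             "volumes", "must be positive")
  check_that(all(diff(volumes) < 0) || length(volumes) == 1L, "volumes",
             "must be strictly decreasing")
  check_that(is.numeric(replicates) && replicates >= 1, "replicates",
             "must be >= 1")
  check_that(is.numeric(p_detect) && p_detect > 0 && p_detect <= 1,
             "p_detect", "must be in (0, 1]")
  check_that(acetate_pos_mean >= 0, "acetate_pos_mean", "must be >= 0")
  check_that(acetate_neg_mean >= 0, "acetate_neg_mean", "must be >= 0")
  structure(
    list(true_density = true_density, volumes = volumes,
         replicates = as.integer(replicates), p_detect = p_detect,
         acetate_pos_mean = acetate_pos_mean,
         acetate_neg_mean = acetate_neg_mean, seed = as.integer(seed)),
    class = "mpn_scenario"
  )
}

#' Depth-profile scenario for the synthetic burial-decay generator
#'
#' Generates abundance-versus-depth records under first-order loss of
#' culturability with burial: `abundance = N0 * 2^(-age / half_life)` with
#' multiplicative log10-normal noise. The synthetic age model is linear
#' (`age = depth / sed_rate`), a stand-in for the radiocarbon age models
#' used on real cores; ages in real data are inputs, not derived.
#'
#' @param N0 surface abundance, per mL sediment.
#' @param half_life culturability half-life, years.
#' @param sed_rate sedimentation rate, cm per yr (only used for the linear
#'   synthetic age model).
#' @param depths sampling depths, cm below seafloor.
#' @param noise_sd_log10 SD of Gaussian noise applied to log10 abundance.
#' @param seed integer seed.
#' @return an object of class `profile_scenario`.
#' @seealso [simulate_depth_profile()], [fit_decay()]
#' @export
profile_scenario <- function(N0 = 4.3e4,
                             half_life = 350,
                             sed_rate = 0.09,
                             depths = c(4, 10, 30, 60, 100, 150, 210, 270),
                             noise_sd_log10 = 0.3,
                             seed = 1L) {
  check_that(is.numeric(N0) && N0 >= 0, "N0", "must be >= 0")
  check_that(is.numeric(half_life) && half_life > 0, "half_life", "must be > 0")
  check_that(is.numeric(sed_rate) && sed_rate > 0, "sed_rate", "must be > 0")
  check_that(is.numeric(depths) && length(depths) >= 1 && all(depths >= 0),
             "depths", "must be >= 0")
  check_that(is.numeric(noise_sd_log10) && noise_sd_log10 >= 0,
             "noise_sd_log10", "must be >= 0")
  structure(
    list(N0 = N0, half_life = half_life, sed_rate = sed_rate,
         depths = depths, noise_sd_log10 = noise_sd_log10,
         seed = as.integer(seed)),
    class = "profile_scenario"
  )
}
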