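#' Simulate a slurry incubation time course
#'
#' Generates the analyte table a pasteurized-slurry germination experiment
#' produces, under a lag-then-exponential production model. VFA-carbon
#' follows
#' \deqn{C(t) = C_{bg} \quad (t < t_{lag}); \qquad
#'       C(t) = C_{bg} + \frac{q N_0}{\mu}\left(e^{\mu (t - t_{lag})} - 1\right)
#'       \quad (t \ge t_{lag}),}
#' the integral of production by a population growing as
#' `N(t) = N0 * exp(mu * (t - t_lag))`. Per-species concentrations divide the
#' VFA-carbon among species by `vfa_split` and convert back to molar units by
#' each species' carbon count. FISH-countable cells equal `N(t)` after the
#' lag and 0 before (pasteurization leaves no stainable vegetative cells).
#' DPA follows two-phase release:
#' `DPA(t) = dpa_total * (f_past + (1 - f_past) * (1 - exp(-t / tau_dpa)))`.
#' Every analyte receives multiplicative Gaussian noise with CV
#' `noise_cv`, truncated at 0.
#'
#' @param scenario a [slurry_scenario()].
#' @param times sampling times in h, non-negative and ascending.
#' @return a [timecourse()] object whose `$data` has one row per time with
#'   columns `time_h`, one `<species>_mM` column per split species,
#'   `dpa_nM` and `fish_per_ml`.
#' @examples
#' sc <- slurry_scenario(noise_cv = 0)
#' tc <- simulate_slurry_timecourse(sc, seq(0, 5, by = 0.5))
#' timecourse_vfa_carbon(tc)
#' @export
simulate_slurry_timecourse <- function(scenario, times) {
  stopifnot(inherits(scenario, "slurry_scenario"))
  check_that(length(times) > 0, "times", "must be non-empty")
  check_that(all(times >= 0), "times", "must be non-negative")
  check_that(all(diff(times) > 0) || length(times) == 1L, "times",
             "must be strictly ascending")
  s <- scenario
  dt <- pmax(times - s$t_lag, 0)
  # exp(mu*dt) - 1 over mu, stable as mu -> 0 (linear production limit)
  grow <- if (s$mu > 0) expm1(s$mu * dt) / s$mu else dt
  carbon <- s$C_bg + mol_per_ml_to_mM(s$q * s$N0) * grow
  fish <- ifelse(times >= s$t_lag, s$N0 * exp(s$mu * dt), 0)
  dpa <- s$dpa_total * (s$f_past + (1 - s$f_past) * (1 - exp(-times / s$tau_dpa)))

  counts <- vfa_carbon_counts()[names(s$vfa_split)]
  species_mat <- outer(carbon, s$vfa_split / counts)  # mM per species

  noisy <- function(x) {
    if (s$noise_cv == 0) return(x)
    pmax(x * (1 + stats::rnorm(length(x), 0, s$noise_cv)), 0)
  }
  dat <- with_local_seed(s$seed, {
    sp <- apply(species_mat, 2, noisy)
    sp <- matrix(sp, nrow = length(times),
                 dimnames = list(NULL, names(s$vfa_split)))
    data.frame(
      time_h = times,
      stats::setNames(as.data.frame(sp), paste0(names(s$vfa_split), "_mM")),
      dpa_nM = noisy(dpa),
      fish_per_ml = noisy(fish)
    )
  })
  timecourse(dat, slurry = slurry_spec(pasteurized = TRUE))
}

#' Simulate a replicated MPN dilution-tube experiment
#'
#' Seeds each tube with `rpois(1, true_density * volume)` spores; the tube is
#' growth-positive if at least one spore initiates growth (independently with
#' probability `p_detect`). Grown tubes draw acetate from
#' `Normal(acetate_pos_mean, 10% CV)`, blanks from
#' `Normal(acetate_neg_mean, 50% CV)`, both truncated at 0.
#'
#' @param scenario an [mpn_scenario()].
#' @return data.frame with columns `level` (1 = least dilute), `volume_ml`,
#'   `tube`, `spores` (latent seeded count), `grown` (logical) and
#'   `acetate_mM`.
#' @examples
#' tt <- simulate_mpn_tubes(mpn_scenario(true_density = 23,
#'                                       volumes = c(0.1, 0.01, 0.001)))
#' aggregate(grown ~ level, tt, sum)
#' @export
simulate_mpn_tubes <- function(scenario) {
  stopifnot(inherits(scenario, "mpn_scenario"))
  s <- scenario
  n_lev <- length(s$volumes)
  lev <- rep(seq_len(n_lev), each = s$replicates)
  vol <- s$volumes[lev]
  with_local_seed(s$seed, {
    spores <- stats::rpois(length(vol), s$true_density * vol)
    grown <- stats::rbinom(length(vol), 1L,
                           1 - (1 - s$p_detect)^spores) == 1L
    acet <- ifelse(
      grown,
      stats::rnorm(length(vol), s$acetate_pos_mean, 0.10 * s$acetate_pos_mean),
      stats::rnorm(length(vol), s$acetate_neg_mean, 0.50 * s$acetate_neg_mean)
    )
    data.frame(
      level = lev, volume_ml = vol,
      tube = rep(seq_len(s$replicates), times = n_lev),
      spores = spores, grown = grown, acetate_mM = pmax(acet, 0)
    )
  })
}

#' Simulate an abundance-versus-depth profile under burial decay
#'
#' Abundance decays with sediment age as
#' `N0 * 2^(-age / half_life) * 10^eps`, `eps ~ Normal(0, noise_sd_log10)`,
#' with the linear synthetic age model `age = depth / sed_rate`.
#'
#' @param scenario a [profile_scenario()].
#' @return data.frame with columns `depth_cm`, `age_yr`, `abundance_per_ml`
#'   and `detected` (all `TRUE`; non-detects arise in real assays, not in
#'   this generator).
#' @examples
#' simulate_depth_profile(profile_scenario(noise_sd_log10 = 0))
#' @export
simulate_depth_profile <- function(scenario) {
  stopifnot(inherits(scenario, "profile_scenario"))
  s <- scenario
  age <- s$depths / s$sed_rate
  with_local_seed(s$seed, {
    eps <- stats::rnorm(length(age), 0, s$noise_sd_log10)
    data.frame(
      depth_cm = s$depths, age_yr = age,
      abundance_per_ml = s$N0 * 2^(-age / s$half_life) * 10^eps,
      detected = TRUE
    )
  })
}

#' Simulate a DPA standard-addition series
#'
#' Produces fluorescence signals for a sample spiked with known DPA
#' additions: `signal_i = slope * (true_conc + added_i) * (1 + eps_i)`,
#' `eps_i ~ Normal(0, noise_cv)`, truncated at 0. The un-amended point
#' (`added = 0`) must be part of the series.
#'
#' @param true_conc true DPA concentration of the un-amended sample, nM.
#' @param slope instrument response, signal units per nM; must be > 0.
#' @param additions spiked DPA concentrations, nM; must include 0.
#' @param noise_cv relative signal noise.
#' @param seed integer seed.
#' @return data.frame with columns `added_nM` and `signal_au`, of class
#'   `std_addition_series`.
#' @seealso [quantify_standard_addition()]
#' @export
simulate_standard_addition <- function(true_conc, slope,
                                       additions = c(0, 100, 200, 400),
                                       noise_cv = 0, seed = 1L) {
  check_that(is.numeric(true_conc) && true_conc >= 0, "true_conc", "must be >= 0")
  check_that(is.numeric(slope) && slope > 0, "slope", "must be > 0")
  check_that(any(additions == 0), "additions", "must include the un-amended point (0)")
  check_that(all(additions >= 0), "additions", "must be >= 0")
  check_that(noise_cv >= 0, "noise_cv", "must be >= 0")
  sig <- with_local_seed(seed, {
    eps <- if (noise_cv > 0) stats::rnorm(length(additions), 0, noise_cv) else 0
    pmax(slope * (true_conc + additions) * (1 + eps), 0)
  })
  structure(data.frame(added_nM = additions, signal_au = sig),
            class = c("std_addition_series", "data.frame"))
}
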