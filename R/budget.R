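#' Budget parameters for the deposition-flux arithmetic
#'
#' Physical constants of the depositional setting. Defaults describe Aarhus
#' Bay: sedimentation rate 0.09 cm/yr, thermophilic sulfate-reducer
#' endospore abundance 1e4 /mL, mean water depth 15 m, water residence time
#' 12 days, a 100-yr accumulation horizon, and a decay constant
#' corresponding to a 350-yr culturability half-life.
#'
#' @param sed_rate sedimentation rate, cm per yr.
#' @param srb_abundance sulfate-reducing endospore abundance, per mL
#'   sediment (added to the fermentative count for the total thermophilic
#'   endospore flux).
#' @param water_depth mean water depth, m.
#' @param residence_days mean water residence time, days.
#' @param horizon_years accumulation horizon over which the standing
#'   inventory is converted to a deposition rate, yr.
#' @param decay first-order loss constant of culturability, per yr.
#' @return object of class `budget_params`.
#' @export
budget_params <- function(sed_rate = 0.09, srb_abundance = 1e4,
                          water_depth = 15, residence_days = 12,
                          horizon_years = 100, decay = log(2) / 350) {
  check_that(sed_rate > 0, "sed_rate", "must be > 0")
  check_that(srb_abundance >= 0, "srb_abundance", "must be >= 0")
  check_that(water_depth > 0, "water_depth", "must be > 0")
  check_that(residence_days > 0, "residence_days", "must be > 0")
  check_that(horizon_years > 0, "horizon_years", "must be > 0")
  check_that(decay >= 0, "decay", "must be >= 0")
  structure(
    list(sed_rate = sed_rate, srb_abundance = srb_abundance,
         water_depth = water_depth, residence_days = residence_days,
         horizon_years = horizon_years, decay = decay),
    class = "budget_params"
  )
}

#' Fit first-order decay of abundance with sediment age
#'
#' Ordinary least squares of `log(abundance)` on age over detected records —
#' the straight line on a log-linear age plot. Returns the decay constant
#' `lam = -slope`, the age-zero abundance `n0 = exp(intercept)` and the
#' half-life `log(2) / lam`. Non-detects (`detected = FALSE`) and
#' non-positive abundances are excluded from the fit. The fit is unweighted:
#' per-point MPN confidence intervals are asymmetric and often unavailable.
#'
#' @param profile data.frame with columns `age_yr` and `abundance_per_ml`,
#'   and optionally `detected` (logical; default all `TRUE`), e.g. from
#'   [simulate_depth_profile()] or [read_profile_csv()].
#' @return object of class `decay_fit`: `n0` (per mL), `lam` (per yr),
#'   `half_life` (yr), `r_squared`, `n_used`.
#' @examples
#' pr <- data.frame(age_yr = c(0, 350), abundance_per_ml = c(100, 50))
#' fit_decay(pr)$half_life  # 350
#' @export
fit_decay <- function(profile) {
  stopifnot(is.data.frame(profile))
  need <- c("age_yr", "abundance_per_ml")
  miss <- setdiff(need, names(profile))
  if (length(miss) > 0) {
    stop("profile lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  det <- if ("detected" %in% names(profile)) profile$detected else TRUE
  keep <- det & profile$abundance_per_ml > 0
  age <- profile$age_yr[keep]
  ab <- profile$abundance_per_ml[keep]
  check_that(length(age) >= 2 && length(unique(age)) >= 2, "profile",
             "needs >= 2 detected records with distinct ages")
  fit <- stats::lm(log(ab) ~ age)
  lam <- -unname(stats::coef(fit)[2])
  # a slope indistinguishable from 0 over the observed age span (e.g. a
  # constant profile up to rounding) is not a decay
  if (!is.finite(lam) || lam * diff(range(age)) < 1e-10) {
    stop("no decay", call. = FALSE)
  }
  structure(
    list(n0 = exp(unname(stats::coef(fit)[1])), lam = lam,
         half_life = log(2) / lam,
         r_squared = r_squared_lm(fit, log(ab)), n_used = length(age)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("First-order burial decay fit\n")
  cat(sprintf("  n0        : %.3g /mL at age 0\n", x$n0))
  cat(sprintf("  lambda    : %.4g /yr\n", x$lam))
  cat(sprintf("  half-life : %.3g yr (R^2 = %.3f, n = %d)\n",
              x$half_life, x$r_squared, x$n_used))
  invisible(x)
}

#' Endospore deposition flux onto the seafloor
#'
#' Converts a standing surface abundance into an annual areal deposition
#' flux: `F = (n_tfe + srb_abundance) * sed_rate * 1e4` spores per m2 per yr
#' (1e4 cm2 per m2; abundances per cm3 = per mL). With
#' `decay_corrected = TRUE` the flux is multiplied by
#' `lam * T / (1 - exp(-lam * T))`, the factor that recovers a constant
#' deposition rate from a standing inventory that decayed while
#' accumulating over the horizon `T`; it tends to 1 as `lam -> 0`.
#'
#' @param n_tfe fermentative endospore abundance, per mL sediment.
#' @param params a [budget_params()].
#' @param decay_corrected apply the accumulation-decay correction.
#' @return spores per m2 per yr.
#' @examples
#' deposition_flux(6e6, budget_params())                        # ~5.4e9
#' deposition_flux(6e6, budget_params(), decay_corrected = TRUE) # ~6e9
#' @export
deposition_flux <- function(n_tfe, params = budget_params(),
                            decay_corrected = FALSE) {
  stopifnot(inherits(params, "budget_params"))
  check_that(n_tfe >= 0, "n_tfe", "must be >= 0")
  f <- (n_tfe + params$srb_abundance) * params$sed_rate * 1e4
  if (decay_corrected && params$decay > 0) {
    lt <- params$decay * params$horizon_years
    f <- f * lt / (-expm1(-lt))
  }
  f
}

#' Required endospore supply from the water column
#'
#' Number of spores each mL of inflowing seawater must deliver to sustain a
#' given deposition flux: the annual water throughput per m2 of seafloor is
#' `water_depth * 1e6 mL/m3 * 365 / residence_days`, and the supply is
#' `flux / throughput`. Years are 365 days (the 365.25 difference is
#' < 0.1%).
#'
#' @param flux deposition flux, spores per m2 per yr.
#' @param params a [budget_params()].
#' @return spores per mL of exchanged water.
#' @examples
#' seawater_supply(5.41e9, budget_params())  # ~12 spores/mL
#' @export
seawater_supply <- function(flux, params = budget_params()) {
  stopifnot(inherits(params, "budget_params"))
  check_that(flux >= 0, "flux", "must be >= 0")
  throughput <- params$water_depth * 1e6 * (365 / params$residence_days)
  flux / throughput
}

#' Thermophilic share of the total endospore community
#'
#' Percentage of the total endospore pool represented by thermophilic
#' fermentative plus sulfate-reducing endospores.
#'
#' @param n_tfe fermentative endospores, per mL.
#' @param n_srb sulfate-reducing endospores, per mL.
#' @param n_total total endospores, per mL; must be > 0.
#' @return percentage.
#' @examples
#' community_fraction(6e6, 1e4, 1e7)  # ~60%
#' @export
community_fraction <- function(n_tfe, n_srb, n_total) {
  check_that(n_tfe >= 0, "n_tfe", "must be >= 0")
  check_that(n_srb >= 0, "n_srb", "must be >= 0")
  check_that(n_total > 0, "n_total", "must be > 0")
  100 * (n_tfe + n_srb) / n_total
}
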