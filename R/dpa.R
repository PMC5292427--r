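#' Quantify DPA by standard addition
#'
#' Ordinary least squares of fluorescence signal on added DPA concentration;
#' the sample concentration is the magnitude of the x-axis intercept,
#' `intercept / slope`. The series must contain the un-amended point and at
#' least two distinct addition levels, and the fitted slope must be positive
#' (a non-responsive series is an error). A negative fitted concentration
#' (possible under noise when the true concentration is near zero) is
#' clamped to 0 with a warning, since true blanks are expected in
#' unpasteurized samples.
#'
#' @param series data.frame with columns `added_nM` and `signal_au`
#'   (e.g. from [simulate_standard_addition()] or [read_std_addition_csv()]).
#' @param dpa_per_spore mol DPA per endospore used for the spore-count
#'   conversion; the default 2.24e-16 is a literature value and
#'   species-variable, so it is a parameter rather than a constant.
#' @return object of class `dpa_result`: `conc` (nM), `spores_per_ml`,
#'   `r_squared`, `dpa_per_spore`.
#' @examples
#' s <- simulate_standard_addition(50, slope = 2, additions = c(0, 100, 200))
#' quantify_standard_addition(s)  # conc = 50 nM
#' @export
quantify_standard_addition <- function(series, dpa_per_spore = 2.24e-16) {
  stopifnot(is.data.frame(series))
  need <- c("added_nM", "signal_au")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    stop("series lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_that(length(unique(series$added_nM)) >= 2, "series",
             "needs at least 2 distinct addition levels")
  check_that(all(series$signal_au >= 0), "series", "signals must be >= 0")
  fit <- stats::lm(signal_au ~ added_nM, data = series)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-responsive series: fitted slope <= 0", call. = FALSE)
  }
  conc <- intercept / slope
  if (conc < 0) {
    warning("fitted concentration negative; clamped to 0", call. = FALSE)
    conc <- 0
  }
  structure(
    list(conc = conc,
         spores_per_ml = spores_from_dpa(nM_to_mol_per_ml(conc), dpa_per_spore),
         r_squared = r_squared_lm(fit, series$signal_au),
         dpa_per_spore = dpa_per_spore),
    class = "dpa_result"
  )
}

#' @export
print.dpa_result <- function(x, ...) {
  cat("DPA standard-addition result\n")
  cat(sprintf("  concentration : %.4g nM (R^2 = %.4f)\n", x$conc, x$r_squared))
  cat(sprintf("  spores        : %.3g /mL at %.3g mol DPA/spore\n",
              x$spores_per_ml, x$dpa_per_spore))
  invisible(x)
}

#' Convert a DPA amount to an endospore count
#'
#' Divides the released DPA (mol per mL) by the per-spore DPA content.
#'
#' @param dpa_mol_per_ml released DPA, mol per mL; must be >= 0.
#' @param dpa_per_spore mol DPA per endospore; must be > 0.
#' @return spores per mL.
#' @examples
#' spores_from_dpa(5.824e-10)  # ~2.6e6 spores/mL
#' @export
spores_from_dpa <- function(dpa_mol_per_ml, dpa_per_spore = 2.24e-16) {
  check_that(all(dpa_mol_per_ml >= 0), "dpa_mol_per_ml", "must be >= 0")
  check_that(dpa_per_spore > 0, "dpa_per_spore", "must be > 0")
  dpa_mol_per_ml / dpa_per_spore
}

#' Spontaneous germination fraction
#'
#' DPA released without pasteurization relative to the pasteurized release,
#' as a percentage. Compares like-for-like amounts (mol per mL or
#' spore-equivalents).
#'
#' @param dpa_unpasteurized,dpa_pasteurized released DPA amounts; the
#'   pasteurized amount must be > 0.
#' @return percentage.
#' @examples
#' germination_fraction(0.7e6, 2.6e6)  # ~27%
#' @export
germination_fraction <- function(dpa_unpasteurized, dpa_pasteurized) {
  check_that(dpa_unpasteurized >= 0, "dpa_unpasteurized", "must be >= 0")
  check_that(dpa_pasteurized > 0, "dpa_pasteurized", "must be > 0")
  100 * dpa_unpasteurized / dpa_pasteurized
}
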