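#' Unit conversions for concentration-based enumeration
#'
#' All concentrations in this package are stored in mM (mmol per litre).
#' Enumeration arithmetic needs mol per mL; these helpers centralize the
#' conversion so factors of 1e3/1e6 never appear inline in analysis code.
#'
#' @param x numeric, concentration in mM (or mol per mL for the inverse).
#' @return numeric of the same length in the target unit.
#' @examples
#' mM_to_mol_per_ml(1.3)  # 1.3e-06
#' @export
mM_to_mol_per_ml <- function(x) x * 1e-6

#' @rdname mM_to_mol_per_ml
#' @export
mol_per_ml_to_mM <- function(x) x * 1e6

#' @rdname mM_to_mol_per_ml
#' @export
nM_to_mol_per_ml <- function(x) x * 1e-12

# internal: stop with the offending field named, for scenario validation
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  invisible(TRUE)
}

# internal: coefficient of determination without summary.lm's
# perfect-fit warning (noiseless synthetic data fits exactly)
r_squared_lm <- function(fit, y) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

# internal: run code under a local, seeded RNG without disturbing the
# caller's RNG state. All generators are routed through this.
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid `seed`: must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
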