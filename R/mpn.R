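#' MPN dilution-series design
#'
#' A most-probable-number design records, per dilution level, the volume of
#' original sample in each tube, the number of replicate tubes, and the
#' number scored growth-positive.
#'
#' Volume accounting matters: in a ten-fold series made by carrying 1 mL
#' through 9-mL blanks, the 10^-n tube contains `10^(1-n)` mL of original
#' sample. The estimator works directly on explicit volumes, so any
#' label-to-volume convention can be expressed.
#'
#' @param volume per-tube volume of original sample, mL (> 0), one per level.
#' @param tubes replicate tubes per level (>= 1).
#' @param positives growth-positive tubes per level (0 <= positives <= tubes).
#' @return object of class `mpn_design` (a data.frame).
#' @examples
#' mpn_design(c(0.1, 0.01, 0.001), 3, c(3, 0, 0))
#' @export
mpn_design <- function(volume, tubes, positives) {
  n <- length(volume)
  tubes <- rep_len(as.integer(tubes), n)
  positives <- as.integer(positives)
  check_that(n >= 1, "volume", "needs at least one dilution level")
  check_that(all(volume > 0), "volume", "must be > 0")
  check_that(all(tubes >= 1), "tubes", "must be >= 1")
  check_that(length(positives) == n, "positives", "one count per level")
  check_that(all(positives >= 0 & positives <= tubes), "positives",
             "must satisfy 0 <= positives <= tubes")
  structure(data.frame(volume = volume, tubes = tubes, positives = positives),
            class = c("mpn_design", "data.frame"))
}

#' Score a dilution tube as growth-positive
#'
#' A tube is positive iff its acetate concentration strictly exceeds
#' `acetate_threshold` (default 0.60 mM; negative controls in this assay
#' reach at most 0.57 mM). Headspace H2 above `h2_threshold` is reported as
#' a growth-suspected advisory only — in the assay H2 accumulation
#' determines when to terminate incubations, while scoring is by acetate.
#'
#' @param acetate acetate concentration, mM.
#' @param h2 optional headspace H2, ppm.
#' @param acetate_threshold scoring threshold, mM (strict inequality).
#' @param h2_threshold advisory threshold, ppm.
#' @return logical scalar; attribute `growth_suspected` carries the H2
#'   advisory when `h2` is supplied.
#' @examples
#' score_tube(0.70)            # TRUE
#' score_tube(0.57, h2 = 65)   # FALSE (highest negative control observed)
#' score_tube(0.60)            # FALSE: the threshold itself is negative
#' @export
score_tube <- function(acetate, h2 = NULL, acetate_threshold = 0.60,
                       h2_threshold = 1000) {
  check_that(all(acetate >= 0), "acetate", "must be >= 0")
  if (!is.null(h2)) check_that(all(h2 >= 0), "h2", "must be >= 0")
  pos <- acetate > acetate_threshold
  if (!is.null(h2)) attr(pos, "growth_suspected") <- h2 > h2_threshold
  pos
}

# internal: binomial log-likelihood of density D for an MPN design,
# with Poisson seeding probability p_i = 1 - exp(-D v_i)
mpn_loglik <- function(D, design) {
  v <- design$volume; n <- design$tubes; x <- design$positives
  vapply(D, function(d) {
    if (d < 0) return(-Inf)
    if (d == 0) {
      return(if (sum(x) > 0) -Inf else 0)
    }
    p <- -expm1(-d * v)
    sum(x * log(p)) - d * sum((n - x) * v)
  }, numeric(1))
}

#' Maximum-likelihood MPN estimate
#'
#' Estimates the density of culturable organisms from the pattern of
#' positive tubes in a serial-dilution assay. Each tube at level i is
#' positive with probability `p_i = 1 - exp(-D v_i)` (Poisson seeding), and
#' the likelihood across levels is binomial:
#' \deqn{L(D) = \prod_i \binom{n_i}{x_i} p_i^{x_i} (1 - p_i)^{n_i - x_i}.}
#' The maximum is located by solving the score equation with
#' [stats::uniroot()] (relative tolerance 1e-6). 95% confidence limits come
#' from the profile likelihood: the D at which the log-likelihood has
#' dropped 1.92 (`qchisq(0.95, 1) / 2`) from its maximum.
#'
#' Degenerate patterns are handled one-sidedly: all tubes negative gives
#' density 0 with an upper limit only; all tubes positive gives an infinite
#' point estimate with a lower limit only (both from the same 1.92
#' log-likelihood drop, which is slightly conservative one-sided).
#'
#' An alternative large-sample interval (`ci_method = "cochran"`) uses the
#' classical log10-normal error for ten-fold designs,
#' `SE(log10 MPN) = 0.58 / sqrt(tubes per level)`.
#'
#' @param design an [mpn_design()].
#' @param conf confidence level (default 0.95).
#' @param ci_method `"profile"` (default) or `"cochran"`.
#' @return object of class `mpn_estimate`: `density`, `ci_low`, `ci_high`
#'   (per mL), `loglik` at the optimum, and `status` (`"ok"`,
#'   `"all_negative"` or `"all_positive"`).
#' @examples
#' mpn_ml(mpn_design(c(0.1, 0.01, 0.001), 3, c(3, 0, 0)))   # ~23 /mL
#' mpn_ml(mpn_design(c(1e-4, 1e-5, 1e-6), 3, c(3, 1, 0)))   # ~4.3e4 /mL
#' @export
mpn_ml <- function(design, conf = 0.95, ci_method = c("profile", "cochran")) {
  stopifnot(inherits(design, "mpn_design"))
  ci_method <- match.arg(ci_method)
  v <- design$volume; n <- design$tubes; x <- design$positives
  drop <- stats::qchisq(conf, df = 1) / 2

  if (sum(x) == 0L) {
    # loglik(D) = -D * sum(n v); one-sided upper limit from the 1.92 drop
    return(structure(
      list(density = 0, ci_low = 0, ci_high = drop / sum(n * v),
           loglik = 0, status = "all_negative"),
      class = "mpn_estimate"
    ))
  }
  if (all(x == n)) {
    # likelihood increases to 0 as D -> Inf; lower limit from the drop
    g <- function(d) mpn_loglik(d, design) + drop
    lo <- stats::uniroot(g, c(1e-12 / max(v), 1e12 / min(v)),
                         tol = 1e-12)$root
    return(structure(
      list(density = Inf, ci_low = lo, ci_high = Inf,
           loglik = 0, status = "all_positive"),
      class = "mpn_estimate"
    ))
  }

  # score equation: sum(x v exp(-Dv)/(1 - exp(-Dv))) = sum((n - x) v);
  # strictly decreasing in D, so the root is the unique maximum
  score <- function(d) {
    p <- -expm1(-d * v)
    sum(x * v * exp(-d * v) / p) - sum((n - x) * v)
  }
  d0 <- sum(x) / sum(n * v)  # crude Poisson start for bracketing
  lo <- d0; hi <- d0
  while (score(lo) < 0) lo <- lo / 10
  while (score(hi) > 0) hi <- hi * 10
  dhat <- stats::uniroot(score, c(lo, hi), tol = d0 * 1e-9)$root
  llmax <- mpn_loglik(dhat, design)

  if (ci_method == "profile") {
    g <- function(d) mpn_loglik(d, design) - (llmax - drop)
    ci_lo <- stats::uniroot(g, c(dhat * 1e-8, dhat), tol = dhat * 1e-9)$root
    ci_hi <- stats::uniroot(g, c(dhat, dhat * 1e8), tol = dhat * 1e-9)$root
  } else {
    se <- 0.58 / sqrt(mean(n))  # Cochran: per ten-fold step, log10 scale
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ci_lo <- dhat * 10^(-z * se)
    ci_hi <- dhat * 10^(z * se)
  }
  structure(
    list(density = dhat, ci_low = ci_lo, ci_high = ci_hi,
         loglik = llmax, status = "ok"),
    class = "mpn_estimate"
  )
}

#' @export
print.mpn_estimate <- function(x, ...) {
  cat("Maximum-likelihood MPN estimate\n")
  cat(sprintf("  density : %s /mL (%s)\n", format(mpn_round(x$density)),
              x$status))
  cat(sprintf("  95%% CI  : %.3g - %.3g /mL\n", x$ci_low, x$ci_high))
  invisible(x)
}

#' Round an MPN density for reporting
#'
#' Report convention: below 100 per mL, nearest integer; otherwise two
#' significant figures.
#'
#' @param density numeric density per mL.
#' @return rounded density.
#' @examples
#' mpn_round(23.06)   # 23
#' mpn_round(42608)   # 43000
#' @export
mpn_round <- function(density) {
  ifelse(is.finite(density) & density < 100,
         round(density), signif(density, 2))
}

#' Score tube readings and estimate MPN density
#'
#' Composition of [score_tube()] and [mpn_ml()]: groups tube readings by
#' dilution level, scores each tube by its acetate concentration, and runs
#' the maximum-likelihood estimator on the resulting design.
#'
#' @param readings data.frame with columns `level`, `volume_ml`,
#'   `acetate_mM` and optionally `h2_ppm` (one row per tube). Replicate
#'   counts and volumes must be consistent within each level.
#' @param acetate_threshold,h2_threshold passed to [score_tube()].
#' @param ... passed to [mpn_ml()].
#' @return an `mpn_estimate`; the scored design is attached as attribute
#'   `design`.
#' @export
mpn_from_tubes <- function(readings, acetate_threshold = 0.60,
                           h2_threshold = 1000, ...) {
  stopifnot(is.data.frame(readings))
  need <- c("level", "volume_ml", "acetate_mM")
  miss <- setdiff(need, names(readings))
  if (length(miss) > 0) {
    stop("tube readings lack columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vol_by_level <- tapply(readings$volume_ml, readings$level,
                         function(v) length(unique(v)))
  check_that(all(vol_by_level == 1L), "readings",
             "volumes must be constant within a dilution level")
  pos <- score_tube(readings$acetate_mM,
                    h2 = readings$h2_ppm,
                    acetate_threshold = acetate_threshold,
                    h2_threshold = h2_threshold)
  df <- data.frame(level = readings$level, volume_ml = readings$volume_ml,
                   positives = as.integer(pos))
  agg <- stats::aggregate(positives ~ level + volume_ml, df, sum)
  agg <- agg[order(-agg$volume_ml), ]
  tubes <- as.integer(table(readings$level)[as.character(agg$level)])
  design <- mpn_design(agg$volume_ml, tubes, agg$positives)
  est <- mpn_ml(design, ...)
  attr(est, "design") <- design
  est
}

#' Extract the informative three-level subset of a larger design
#'
#' Classical MPN tables use three consecutive dilutions: the most dilute
#' level with all tubes positive, followed by the next two levels. This
#' helper extracts that triplet for comparison with table-based reports.
#'
#' @param design an [mpn_design()], ordered from largest to smallest volume.
#' @return an `mpn_design` with (up to) three rows.
#' @export
mpn_informative_triplet <- function(design) {
  stopifnot(inherits(design, "mpn_design"))
  design <- design[order(-design$volume), ]
  all_pos <- design$positives == design$tubes
  start <- if (any(all_pos)) max(which(all_pos)) else 1L
  rows <- seq(start, min(start + 2L, nrow(design)))
  mpn_design(design$volume[rows], design$tubes[rows], design$positives[rows])
}
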