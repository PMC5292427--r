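#' Generate every pipeline input table from scenario files
#'
#' Runs the seeded generators and writes their CSVs: a slurry time course, an
#' MPN tube table, a depth profile and a DPA standard-addition series. With
#' identical scenarios and seeds the written files are byte-identical.
#'
#' @param out_dir output directory (created if missing).
#' @param slurry,mpn,profile scenario objects (or paths to scenario YAML
#'   files) for the three generators; `NULL` skips a generator.
#' @param times sampling times for the slurry time course, h.
#' @param std_addition list of arguments for
#'   [simulate_standard_addition()]; `NULL` skips it.
#' @return named character vector of the files written.
#' @export
simulate_inputs <- function(out_dir,
                            slurry = slurry_scenario(),
                            mpn = mpn_scenario(),
                            profile = profile_scenario(),
                            times = seq(0, 5, by = 0.25),
                            std_addition = list(true_conc = 582.4, slope = 2,
                                                noise_cv = 0.02, seed = 1L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  as_scn <- function(x) if (is.character(x)) read_scenario(x) else x
  files <- character()
  if (!is.null(slurry)) {
    tc <- simulate_slurry_timecourse(as_scn(slurry), times)
    f <- file.path(out_dir, "timecourse.csv")
    write_timecourse_csv(tc, f)
    files["timecourse"] <- f
  }
  if (!is.null(mpn)) {
    tubes <- simulate_mpn_tubes(as_scn(mpn))
    f <- file.path(out_dir, "mpn_tubes.csv")
    write_mpn_tubes_csv(tubes, f)
    files["mpn_tubes"] <- f
  }
  if (!is.null(profile)) {
    pr <- simulate_depth_profile(as_scn(profile))
    f <- file.path(out_dir, "profile.csv")
    write_profile_csv(pr, f)
    files["profile"] <- f
  }
  if (!is.null(std_addition)) {
    ser <- do.call(simulate_standard_addition, std_addition)
    f <- file.path(out_dir, "std_addition.csv")
    write_std_addition_csv(ser, f)
    files["std_addition"] <- f
  }
  files
}

#' Run the full enumeration and budget pipeline
#'
#' Wires the analysis stages end to end and collects their results in one
#' report. Stages run independently: a failure in one is recorded under
#' `errors` and the remaining stages still run.
#'
#' Stages (each optional, enabled by supplying its input):
#' * kinetics: onset detection, anchored exponential fit, cell-specific
#'   rate (from the FISH count at the end of the fit window) and abundance
#'   per mL slurry and sediment.
#' * mpn: tube scoring and maximum-likelihood density with 95% CI.
#' * dpa: standard-addition quantification and spore-equivalent count.
#' * decay: first-order decay fit of a depth profile (half-life).
#' * budget: deposition flux (uncorrected and decay-corrected), required
#'   seawater supply, and community fraction.
#'
#' @param timecourse a [timecourse()] or path to a time-course CSV.
#' @param mpn_tubes data.frame of tube readings or path to a tube CSV.
#' @param std_addition data.frame or path to a standard-addition CSV.
#' @param profile data.frame or path to a depth-profile CSV.
#' @param slurry [slurry_spec()] used when reading a time-course path and
#'   for the sediment conversion.
#' @param q cell-specific rate (mol C per cell per h) for the abundance
#'   step; if `NULL`, calibrated from the time course's own FISH counts.
#' @param fit_window,baseline_window h, passed to [fit_exponential()].
#' @param acetate_threshold,h2_threshold passed to [mpn_from_tubes()].
#' @param params [budget_params()] for the budget stage.
#' @param n_total total endospore abundance per mL for the community
#'   fraction (`NA` skips that line).
#' @return object of class `run_report`: a list with one element per stage,
#'   plus `version`, `timestamp` and `errors`.
#' @export
run_quantification <- function(timecourse = NULL, mpn_tubes = NULL,
                               std_addition = NULL, profile = NULL,
                               slurry = slurry_spec(), q = NULL,
                               fit_window = c(3.5, 5),
                               baseline_window = c(0, 3.5),
                               acetate_threshold = 0.60, h2_threshold = 1000,
                               params = budget_params(), n_total = 1e7) {
  if (is.null(timecourse) && is.null(mpn_tubes) && is.null(std_addition) &&
      is.null(profile)) {
    stop("no inputs: supply at least one of timecourse, mpn_tubes, ",
         "std_addition, profile", call. = FALSE)
  }
  report <- list(version = as.character(utils::packageVersion("sporeflux")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  n_sediment <- NULL
  if (!is.null(timecourse)) {
    report$kinetics <- run_stage("kinetics", {
      tc <- if (is.character(timecourse)) {
        read_timecourse_csv(timecourse, slurry = slurry)
      } else timecourse
      onset <- tryCatch(detect_onset(tc, baseline_window), error = function(e) NA)
      fit <- fit_exponential(tc, fit_window, baseline_window)
      q_used <- q
      if (is.null(q_used)) {
        if (!"fish_per_ml" %in% names(tc$data)) {
          stop("no `q` given and time course has no FISH counts", call. = FALSE)
        }
        i <- max(which(tc$data$time_h <= fit_window[2] &
                         tc$data$fish_per_ml > 0))
        rate_i <- fit$k * fit$C0 * exp(fit$k * (tc$data$time_h[i] - fit$t_on))
        q_used <- cell_specific_rate(rate_i, tc$data$fish_per_ml[i])
      }
      ab <- abundance_from_rate(fit$r_on, q_used, tc$slurry)
      list(onset_h = onset, fit = fit, abundance = ab)
    })
    if (!is.null(report$kinetics)) {
      n_sediment <- report$kinetics$abundance$n_sediment
    }
  }

  if (!is.null(mpn_tubes)) {
    report$mpn <- run_stage("mpn", {
      tubes <- if (is.character(mpn_tubes)) read_mpn_tubes_csv(mpn_tubes) else mpn_tubes
      mpn_from_tubes(tubes, acetate_threshold = acetate_threshold,
                     h2_threshold = h2_threshold)
    })
  }

  if (!is.null(std_addition)) {
    report$dpa <- run_stage("dpa", {
      ser <- if (is.character(std_addition)) read_std_addition_csv(std_addition) else std_addition
      quantify_standard_addition(ser)
    })
  }

  if (!is.null(profile)) {
    report$decay <- run_stage("decay", {
      pr <- if (is.character(profile)) read_profile_csv(profile) else profile
      fit_decay(pr)
    })
  }

  if (!is.null(n_sediment)) {
    report$budget <- run_stage("budget", {
      if (!is.null(report$decay)) {
        params$decay <- report$decay$lam
      }
      flux <- deposition_flux(n_sediment, params)
      flux_corr <- deposition_flux(n_sediment, params, decay_corrected = TRUE)
      list(
        flux_uncorrected = flux,
        flux_corrected = flux_corr,
        supply_per_ml = seawater_supply(flux, params),
        supply_per_ml_corrected = seawater_supply(flux_corr, params),
        community_pct = if (is.finite(n_total)) {
          community_fraction(n_sediment, params$srb_abundance, n_total)
        } else NA_real_,
        params = params
      )
    })
  }

  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("sporeflux run report (v%s, %s UTC)\n", x$version, x$timestamp))
  kv <- report_flat(x)
  for (k in names(kv)) cat(sprintf("  %-28s %s\n", k, format(kv[[k]])))
  if (length(x$errors) > 0) {
    cat("stage errors:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

#' Flatten a run report to key-value pairs
#'
#' Every reported number is keyed by its stage and quantity, suitable for
#' writing as a flat `key: value` text report.
#'
#' @param report a `run_report` from [run_quantification()].
#' @return named list of scalars.
#' @export
report_flat <- function(report) {
  out <- list()
  if (!is.null(report$kinetics)) {
    k <- report$kinetics
    out$kinetics.onset_h <- k$onset_h
    out$kinetics.k_per_h <- k$fit$k
    out$kinetics.C0_mM <- k$fit$C0
    out$kinetics.r_on_mM_per_h <- k$fit$r_on
    out$kinetics.doubling_min <- k$fit$doubling_time
    out$kinetics.q_mol_per_cell_h <- k$abundance$q_used
    out$kinetics.n_slurry_per_ml <- k$abundance$n_slurry
    out$kinetics.n_sediment_per_ml <- k$abundance$n_sediment
  }
  if (!is.null(report$mpn)) {
    out$mpn.density_per_ml <- report$mpn$density
    out$mpn.ci_low_per_ml <- report$mpn$ci_low
    out$mpn.ci_high_per_ml <- report$mpn$ci_high
    out$mpn.status <- report$mpn$status
  }
  if (!is.null(report$dpa)) {
    out$dpa.conc_nM <- report$dpa$conc
    out$dpa.spores_per_ml <- report$dpa$spores_per_ml
    out$dpa.r_squared <- report$dpa$r_squared
  }
  if (!is.null(report$decay)) {
    out$decay.half_life_yr <- report$decay$half_life
    out$decay.lambda_per_yr <- report$decay$lam
    out$decay.n0_per_ml <- report$decay$n0
  }
  if (!is.null(report$budget)) {
    b <- report$budget
    out$budget.flux_per_m2_yr <- b$flux_uncorrected
    out$budget.flux_corrected_per_m2_yr <- b$flux_corrected
    out$budget.supply_per_ml <- b$supply_per_ml
    out$budget.community_pct <- b$community_pct
  }
  out
}

#' Write a run report as a flat text file
#'
#' @param report a `run_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  kv <- report_flat(report)
  lines <- sprintf("%s: %s", names(kv),
                   vapply(kv, function(v) format(v, digits = 17),
                          character(1)))
  writeLines(lines, path)
  invisible(path)
}
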