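#' File schemas with unit-suffix validation
#'
#' All tabular inputs and outputs are plain CSV with unit-bearing column
#' names (`_h`, `_mM`, `_ppm`, `_nM`, `_per_ml`, `_cm`, `_yr`, `_au`).
#' Readers validate the header before typing the table: a recognised analyte
#' column without its unit suffix is a fatal error (silent unit mistakes are
#' the main failure mode of enumeration arithmetic), while unrecognised
#' extra columns are preserved with a warning.
#'
#' Schemas:
#' * time course: `time_h`, one or more `<species>_mM`, optional `h2_ppm`,
#'   `dpa_nM`, `fish_per_ml`
#' * MPN tubes: `sample_id`, `level`, `volume_ml`, `acetate_mM`,
#'   optional `h2_ppm`
#' * MPN design: `volume_ml`, `tubes`, `positives`
#' * depth profile: `depth_cm`, `age_yr`, `abundance_per_ml`, optional
#'   `ci_low_per_ml`, `ci_high_per_ml`, `detected`
#' * standard addition: `added_nM`, `signal_au`
#'
#' @param path file path.
#' @param slurry a [slurry_spec()] attached to the time course on read.
#' @return the typed table (a [timecourse()] for time courses, an
#'   [mpn_design()] for designs, data.frames otherwise).
#' @name schemas
NULL

# internal: read a CSV after confirming it exists (clean error for typos)
read_csv_checked <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE)
}

# internal: bare analyte names that must carry a unit suffix
.suffixed_stems <- function() {
  c(names(vfa_carbon_counts()), "time", "h2", "dpa", "fish", "volume",
    "acetate", "abundance", "depth", "age", "added", "signal",
    "ci_low", "ci_high")
}

# internal: validate a header against required/optional unit-suffixed names
check_schema <- function(header, required, optional = character(), what) {
  miss <- setdiff(required, header)
  if (length(miss) > 0) {
    stop(sprintf("%s file lacks required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bare <- intersect(header, .suffixed_stems())
  if (length(bare) > 0) {
    stop(sprintf("%s file has columns without unit suffixes: %s", what,
                 paste(bare, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(header, c(required, optional))
  if (length(extra) > 0) {
    warning(sprintf("%s file has extra columns (preserved): %s", what,
                    paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname schemas
#' @export
read_timecourse_csv <- function(path, slurry = slurry_spec()) {
  dat <- read_csv_checked(path)
  species_cols <- paste0(names(vfa_carbon_counts()), "_mM")
  check_schema(names(dat), required = "time_h",
               optional = c(species_cols, "h2_ppm", "dpa_nM", "fish_per_ml"),
               what = "time-course")
  if (length(timecourse_species(dat)) == 0) {
    stop("time-course file has no registered `<species>_mM` column",
         call. = FALSE)
  }
  timecourse(dat, slurry = slurry)
}

#' @rdname schemas
#' @export
write_timecourse_csv <- function(tc, path) {
  stopifnot(inherits(tc, "timecourse"))
  utils::write.csv(tc$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname schemas
#' @export
read_mpn_tubes_csv <- function(path) {
  dat <- read_csv_checked(path)
  check_schema(names(dat),
               required = c("sample_id", "level", "volume_ml", "acetate_mM"),
               optional = "h2_ppm", what = "MPN tube")
  dat
}

#' @rdname schemas
#' @export
write_mpn_tubes_csv <- function(tubes, path, sample_id = "sample") {
  stopifnot(is.data.frame(tubes))
  out <- data.frame(sample_id = sample_id, level = tubes$level,
                    volume_ml = tubes$volume_ml,
                    acetate_mM = tubes$acetate_mM)
  if ("h2_ppm" %in% names(tubes)) out$h2_ppm <- tubes$h2_ppm
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname schemas
#' @export
read_mpn_design_csv <- function(path) {
  dat <- read_csv_checked(path)
  check_schema(names(dat), required = c("volume_ml", "tubes", "positives"),
               what = "MPN design")
  mpn_design(dat$volume_ml, dat$tubes, dat$positives)
}

#' @rdname schemas
#' @export
write_mpn_design_csv <- function(design, path) {
  stopifnot(inherits(design, "mpn_design"))
  utils::write.csv(
    data.frame(volume_ml = design$volume, tubes = design$tubes,
               positives = design$positives),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname schemas
#' @export
read_profile_csv <- function(path) {
  dat <- read_csv_checked(path)
  check_schema(names(dat),
               required = c("depth_cm", "age_yr", "abundance_per_ml"),
               optional = c("ci_low_per_ml", "ci_high_per_ml", "detected"),
               what = "depth-profile")
  if (!"detected" %in% names(dat)) dat$detected <- TRUE
  dat$detected <- as.logical(dat$detected)
  dat
}

#' @rdname schemas
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(is.data.frame(profile))
  utils::write.csv(profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname schemas
#' @export
read_std_addition_csv <- function(path) {
  dat <- read_csv_checked(path)
  check_schema(names(dat), required = c("added_nM", "signal_au"),
               what = "standard-addition")
  dat
}

#' @rdname schemas
#' @export
write_std_addition_csv <- function(series, path) {
  stopifnot(is.data.frame(series))
  utils::write.csv(series[c("added_nM", "signal_au")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a scenario configuration file
#'
#' Scenarios are stored one per file as `key: value` YAML. The `type` key
#' selects the constructor: `slurry`, `mpn` or `profile`; remaining keys are
#' passed to [slurry_scenario()], [mpn_scenario()] or [profile_scenario()].
#'
#' @param path file path.
#' @param scenario a scenario object (for writing).
#' @return the scenario object (reading) or `path` invisibly (writing).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  type <- cfg$type
  cfg$type <- NULL
  ctor <- switch(type %||% "",
                 slurry = slurry_scenario,
                 mpn = mpn_scenario,
                 profile = profile_scenario,
                 stop("scenario `type` must be slurry, mpn or profile",
                      call. = FALSE))
  if (!is.null(cfg$vfa_split)) cfg$vfa_split <- unlist(cfg$vfa_split)
  if (!is.null(cfg$volumes)) cfg$volumes <- unlist(cfg$volumes)
  if (!is.null(cfg$depths)) cfg$depths <- unlist(cfg$depths)
  do.call(ctor, cfg)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  type <- switch(class(scenario)[1],
                 slurry_scenario = "slurry", mpn_scenario = "mpn",
                 profile_scenario = "profile",
                 stop("not a scenario object", call. = FALSE))
  out <- c(list(type = type), unclass(scenario))
  if (!is.null(out$vfa_split)) out$vfa_split <- as.list(out$vfa_split)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
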