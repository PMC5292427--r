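#' Registry of volatile fatty acid species and their carbon counts
#'
#' Fermentation products are compared on a common VFA-carbon scale: the molar
#' concentration of each volatile fatty acid weighted by the number of carbon
#' atoms per molecule. This registry defines the species the package knows
#' and their carbon counts.
#'
#' @return named integer vector, species name to carbon atoms per molecule.
#' @examples
#' vfa_carbon_counts()[["acetate"]]  # 2
#' @export
vfa_carbon_counts <- function() {
  c(
    formate = 1L, acetate = 2L, propionate = 3L, lactate = 3L,
    butyrate = 4L, isobutyrate = 4L, valerate = 5L, isovalerate = 5L
  )
}

#' Total VFA-carbon of a set of VFA concentrations
#'
#' Sums molar concentrations weighted by carbon atoms per molecule, i.e.
#' `sum(conc_i * carbon_i)` over the named species.
#'
#' @param vfa_map named numeric vector or list, species name -> concentration
#'   in mM. May be empty.
#' @return VFA-carbon concentration in mM C (scalar).
#' @examples
#' vfa_carbon(c(acetate = 1.0))                               # 2.0
#' vfa_carbon(c(acetate = 0.5, propionate = 0.2, formate = 0.1))  # 1.7
#' @export
vfa_carbon <- function(vfa_map) {
  vfa_map <- unlist(vfa_map)
  if (length(vfa_map) == 0L) return(0)
  reg <- vfa_carbon_counts()
  unknown <- setdiff(names(vfa_map), names(reg))
  if (length(unknown) > 0L) {
    stop("unknown VFA species: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(vfa_map < 0)) stop("VFA concentrations must be >= 0", call. = FALSE)
  sum(vfa_map * reg[names(vfa_map)])
}
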