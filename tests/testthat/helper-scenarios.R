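# Shared fixtures: noiseless study-condition scenarios and small helpers.

noiseless_slurry <- function(...) {
  slurry_scenario(noise_cv = 0, ...)
}

default_times <- seq(0, 5, by = 0.25)

# grid-search oracle for the MPN likelihood: argmax over a dense log-spaced
# grid, independent of the root-finding path used by mpn_ml()
mpn_grid_oracle <- function(design, center, decades = 6, n = 2000) {
  grid <- 10^seq(log10(center) - decades / 2, log10(center) + decades / 2,
                 length.out = n)
  ll <- vapply(grid, function(d) {
    p <- 1 - exp(-d * design$volume)
    sum(design$positives * log(p)) -
      d * sum((design$tubes - design$positives) * design$volume)
  }, numeric(1))
  grid[which.max(ll)]
}

# random non-degenerate MPN design (some positives, not saturated)
random_design <- function() {
  repeat {
    v0 <- 10^stats::runif(1, -3, 1)
    volumes <- v0 * 10^-(0:(sample(2:4, 1)))
    tubes <- sample(2:5, 1)
    d <- 10^stats::runif(1, 0, 4)
    p <- 1 - exp(-d * volumes)
    pos <- stats::rbinom(length(volumes), tubes, p)
    if (sum(pos) > 0 && any(pos < tubes)) {
      return(mpn_design(volumes, tubes, pos))
    }
  }
}
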