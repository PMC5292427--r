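test_that("slurry time course follows the lag-then-exponential model", {
  sc <- noiseless_slurry()
  tc <- simulate_slurry_timecourse(sc, default_times)
  carbon <- timecourse_vfa_carbon(tc)

  # before and at onset the curve sits exactly on the baseline
  expect_equal(carbon[default_times <= sc$t_lag],
               rep(sc$C_bg, sum(default_times <= sc$t_lag)))

  # instantaneous production rate at onset is q*N0 (1.28 mM C/h for the
  # default 2e6 cells/mL at 640 fmol C/cell/h), checked against the
  # analytic derivative via a small finite difference
  eps <- 1e-6
  tc2 <- simulate_slurry_timecourse(sc, c(sc$t_lag, sc$t_lag + eps))
  slope <- diff(timecourse_vfa_carbon(tc2)) / eps
  expect_equal(slope, 1.28, tolerance = 1e-4)
  expect_equal(mol_per_ml_to_mM(sc$q * sc$N0), 1.28)

  # FISH counts track N0 * exp(mu * (t - t_lag)) after onset, 0 before
  expect_equal(tc$data$fish_per_ml[default_times < sc$t_lag],
               rep(0, sum(default_times < sc$t_lag)))
  expect_equal(tc$data$fish_per_ml[default_times >= sc$t_lag],
               sc$N0 * exp(sc$mu * (default_times[default_times >= sc$t_lag] - sc$t_lag)))
})

test_that("mu -> 0 limit of the slurry model is linear production", {
  sc <- noiseless_slurry(mu = 0, C_bg = 0.5)
  tc <- simulate_slurry_timecourse(sc, c(0, 4, 5))
  carbon <- timecourse_vfa_carbon(tc)
  expect_equal(carbon[2], sc$C_bg + mol_per_ml_to_mM(sc$q * sc$N0) * 0.5)
  expect_equal(carbon[3], sc$C_bg + mol_per_ml_to_mM(sc$q * sc$N0) * 1.5)
})

test_that("per-species concentrations recombine to the VFA-carbon curve", {
  sc <- noiseless_slurry()
  tc <- simulate_slurry_timecourse(sc, default_times)
  dt <- pmax(default_times - sc$t_lag, 0)
  expected <- sc$C_bg + mol_per_ml_to_mM(sc$q * sc$N0) * expm1(sc$mu * dt) / sc$mu
  expect_equal(timecourse_vfa_carbon(tc), expected)
})

test_that("DPA release has two phases and saturates at the pool size", {
  sc <- noiseless_slurry()
  tc <- simulate_slurry_timecourse(sc, c(0, 0.15, 5))
  dpa <- tc$data$dpa_nM
  expect_equal(dpa[1], sc$dpa_total * sc$f_past)        # pasteurization share
  expect_gt(dpa[2], dpa[1])                             # post-heating release
  expect_equal(dpa[3], sc$dpa_total, tolerance = 1e-9)  # saturated by 5 h
})

test_that("generators are bit-identical under the same seed", {
  sc <- slurry_scenario(noise_cv = 0.05, seed = 42)
  expect_identical(simulate_slurry_timecourse(sc, default_times),
                   simulate_slurry_timecourse(sc, default_times))
  ms <- mpn_scenario(seed = 42)
  expect_identical(simulate_mpn_tubes(ms), simulate_mpn_tubes(ms))
  ps <- profile_scenario(seed = 42)
  expect_identical(simulate_depth_profile(ps), simulate_depth_profile(ps))
  expect_identical(simulate_standard_addition(50, 2, noise_cv = 0.05, seed = 42),
                   simulate_standard_addition(50, 2, noise_cv = 0.05, seed = 42))
  # and the generators do not disturb the caller's RNG stream
  set.seed(7); a <- runif(1)
  set.seed(7); invisible(simulate_mpn_tubes(ms)); b <- runif(1)
  expect_identical(a, b)
})

test_that("noiseless VFA-carbon is non-decreasing and scales with N0", {
  sc <- noiseless_slurry()
  carbon <- timecourse_vfa_carbon(simulate_slurry_timecourse(sc, default_times))
  expect_true(all(diff(carbon) >= 0))

  # initial production rate scales with N0 (dilution scaling)
  for (f in c(0.1, 0.5, 2)) {
    sc_f <- noiseless_slurry(N0 = sc$N0 * f, C_bg = sc$C_bg)
    eps <- 1e-6
    rate <- function(s) {
      diff(timecourse_vfa_carbon(
        simulate_slurry_timecourse(s, c(s$t_lag, s$t_lag + eps)))) / eps
    }
    expect_equal(rate(sc_f) / rate(sc), f, tolerance = 1e-4)
  }
})

test_that("MPN tube generator matches its Poisson seeding model", {
  # degenerate densities
  none <- simulate_mpn_tubes(mpn_scenario(true_density = 0,
                                          volumes = c(0.1, 0.01, 0.001)))
  expect_true(all(!none$grown))
  lots <- simulate_mpn_tubes(mpn_scenario(true_density = 1e9,
                                          volumes = c(0.1, 0.01, 0.001)))
  expect_true(all(lots$grown))

  # fraction of positive tubes at v = 0.1 mL, density 23/mL over many
  # replicate experiments approaches 1 - exp(-2.3) ~ 0.90
  pos <- vapply(1:10000, function(i) {
    tt <- simulate_mpn_tubes(mpn_scenario(true_density = 23,
                                          volumes = c(0.1, 0.01, 0.001),
                                          seed = i))
    mean(tt$grown[tt$level == 1])
  }, numeric(1))
  expect_equal(mean(pos), 1 - exp(-2.3), tolerance = 0.01)

  # positive fraction is non-decreasing in true density
  frac <- vapply(c(1, 10, 100, 1000), function(d) {
    tt <- simulate_mpn_tubes(mpn_scenario(true_density = d,
                                          volumes = c(0.1, 0.01, 0.001),
                                          replicates = 100, seed = 1))
    mean(tt$grown)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))

  # grown and blank tubes separate on acetate signal
  tt <- simulate_mpn_tubes(mpn_scenario(true_density = 1e3, seed = 3))
  expect_true(min(tt$acetate_mM[tt$grown]) >
                max(tt$acetate_mM[!tt$grown]))
})

test_that("depth profile generator follows half-life decay with linear ages", {
  ps <- profile_scenario(N0 = 4.3e4, half_life = 350, sed_rate = 0.09,
                         depths = c(0, 31.5, 270), noise_sd_log10 = 0)
  pr <- simulate_depth_profile(ps)
  expect_equal(pr$age_yr, c(0, 350, 3000))
  expect_equal(pr$abundance_per_ml[1], 4.3e4)
  expect_equal(pr$abundance_per_ml[2], 4.3e4 / 2)       # one half-life
  expect_equal(pr$abundance_per_ml[3], 4.3e4 * 2^(-3000 / 350))
  expect_equal(pr$abundance_per_ml[3], 113, tolerance = 0.01)
})

test_that("standard-addition generator is exact at zero noise", {
  s0 <- simulate_standard_addition(0, 2, c(0, 100, 200), 0)
  expect_equal(s0$signal_au, c(0, 200, 400))  # zero intercept through origin
  s1 <- simulate_standard_addition(50, 2, c(0, 100, 200), 0)
  expect_equal(s1$signal_au / 2, c(50, 150, 250))
})

test_that("scenario validation names the offending field", {
  expect_error(slurry_scenario(N0 = -1), "N0")
  expect_error(slurry_scenario(f_past = 1.5), "f_past")
  expect_error(slurry_scenario(vfa_split = c(acetate = 0.5)), "vfa_split")
  expect_error(mpn_scenario(volumes = c(0.01, 0.1)), "volumes")
  expect_error(mpn_scenario(p_detect = 0), "p_detect")
  expect_error(profile_scenario(half_life = 0), "half_life")
  expect_error(profile_scenario(sed_rate = -1), "sed_rate")
  expect_error(simulate_standard_addition(50, 0), "slope")
  expect_error(simulate_standard_addition(50, 2, additions = c(100, 200)),
               "additions")
  expect_error(
    simulate_slurry_timecourse(noiseless_slurry(), numeric(0)), "times")
  expect_error(
    simulate_slurry_timecourse(noiseless_slurry(), c(2, 1)), "times")
})
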