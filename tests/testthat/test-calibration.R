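test_that("washout rate, sphere volume and admissible r-range match hand arithmetic", {
  expect_equal(round(washout_from_halflife(2.8), 2), 5.94)
  expect_equal(washout_from_halflife(24 * log(2)), 1)
  # halving the half-life doubles the rate
  expect_equal(washout_from_halflife(1.4), 2 * washout_from_halflife(2.8))
  expect_error(washout_from_halflife(0), "t_half must be")

  expect_equal(sphere_volume(15), pi / 6 * 15^3)
  expect_equal(round(sphere_volume(15)), 1767)
  expect_equal(sphere_volume(0), 0)
  expect_equal(sphere_volume(2), 4 * pi / 3)

  rr <- admissible_r_range(150, 1500, 5.94, c(50, 360))
  expect_equal(rr$r_low, 150 * 5.94 / 50)    # 17.82
  expect_equal(rr$r_high, 1500 * 5.94 / 360) # 24.75
  rr1 <- admissible_r_range(150, 1500, 5.94, 50)
  expect_equal(c(rr1$r_low, rr1$r_high), c(17.82, 178.2))
  # degenerate point interval
  pt <- admissible_r_range(100, 100, 2, 50)
  expect_equal(pt$r_low, pt$r_high)
  # disjoint per-arm intervals signal no admissible r without erroring
  none <- admissible_r_range(100, 110, 1, c(1, 1000))
  expect_false(none$admissible)
  expect_true(is.na(none$r_low))
})

test_that("the objective discriminates and vanishes on noise-free data", {
  truth <- base_params()
  ms0 <- generate_experiment(truth, noise = noise_model(sigma_rel = 0), seed = 1)
  expect_lt(calib_objective(truth, ms0), 1e-2)
  # perturbing any fitted parameter off the truth raises the objective
  expect_gt(calib_objective(base_params(k1 = 0.55 * 1.1), ms0), 1)
  expect_gt(calib_objective(base_params(a1 = 43 * 1.1), ms0), 1)

  # invariance to record order and replicate relabeling
  ms <- generate_experiment(truth, seed = 4)
  o1 <- calib_objective(truth, ms)
  shuffled <- ms[sample(nrow(ms)), ]
  shuffled$replicate <- rev(shuffled$replicate)
  expect_equal(calib_objective(truth, shuffled), o1)

  # chi-squared behavior: objective at the truth is near the record count
  objs <- vapply(1:6, function(s) {
    calib_objective(truth, generate_experiment(truth, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(objs) - nrow(ms)), 3 * sqrt(2 * nrow(ms) / 6))
})

test_that("noise-free calibration recovers the generating parameters", {
  truth <- base_params()
  ms0 <- generate_experiment(truth, noise = noise_model(sigma_rel = 0), seed = 1)
  fit <- fit_model(ms0, n_starts = 8, seed = 1)
  expect_true(fit$converged)
  expect_lt(rel_diff(fit$estimates[["k1"]], 0.55), 0.01)
  expect_lt(rel_diff(fit$estimates[["a1"]], 43), 0.01)
  expect_lt(rel_diff(fit$estimates[["alpha"]], 1.7e-6), 0.01)
  expect_lt(fit$objective, 1e-2)

  # single start launched from the truth stays at the noiseless minimum
  fit1 <- fit_model(ms0, n_starts = 1, seed = 1,
                    start = c(k1 = 0.55, a1 = 43, alpha = 1.7e-6))
  expect_lt(fit1$objective, 1e-2)
})

test_that("fits are deterministic for a fixed seed", {
  ms <- generate_experiment(seed = 6)
  f1 <- fit_model(ms, n_starts = 4, seed = 42)
  f2 <- fit_model(ms, n_starts = 4, seed = 42)
  expect_identical(f1$estimates, f2$estimates)
})

test_that("profile likelihood flags identifiable and degenerate designs", {
  ms <- generate_experiment(seed = 1)
  spec <- calibration_spec()
  fit <- fit_model(ms, n_starts = 4, seed = 1)

  pk <- profile_likelihood(ms, spec, fit, "k1")
  # the profile minimum sits at (or numerically below) the best objective
  expect_lte(min(pk$objective), fit$objective + 1e-6)
  expect_equal(pk$verdict, "identifiable")
  expect_true(pk$ci[["lower"]] < fit$estimates[["k1"]] &&
                fit$estimates[["k1"]] < pk$ci[["upper"]])

  # a single-time-point design cannot pin down the growth curve: at least
  # one parameter profile stays open
  flat <- generate_experiment(days = 10, seed = 1)
  ffit <- fit_model(flat, n_starts = 4, seed = 1)
  verdicts <- vapply(c("k1", "a1", "alpha"), function(pn) {
    profile_likelihood(flat, spec, ffit, pn)$verdict
  }, character(1))
  expect_true(any(verdicts != "identifiable"))
})

test_that("profile intervals cover the truth across replicate experiments", {
  hits <- vapply(1:10, function(s) {
    ms <- generate_experiment(seed = s)
    fit <- fit_model(ms, n_starts = 4, seed = s)
    ci <- profile_likelihood(ms, calibration_spec(), fit, "k1")$ci
    ci[["lower"]] <= 0.55 && 0.55 <= ci[["upper"]]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("calibration specs validate their structure", {
  expect_error(calibration_spec(free = c("k1", "zeta")), "unknown free")
  expect_error(calibration_spec(free = c("k1", "mu")), "overlap")
  expect_error(calibration_spec(bounds = c(0, 10)), "bounds must be positive")
})
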