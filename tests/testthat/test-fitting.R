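# Calibration fitting strategies: recovery on noiseless data, closed forms,
# exactly-determined solvers, the two-step batch procedure, and failure
# modes.

test_that("full fit recovers generating parameters from eight noiseless points", {
  truth <- calibration_params(247, 3585, 30.80)
  fit <- fit_full(noiseless_dataset(truth, background = 247))
  expect_equal(coef(fit), coef(truth), tolerance = 1e-4)
  expect_lt(fit$rms, 1e-6)
})

test_that("full fit with free background recovers all three parameters", {
  truth <- calibration_params(240, 3577, 33.58)
  d <- noiseless_dataset(truth, background = NULL)
  fit <- fit_full(d, fix_p0 = FALSE)
  expect_equal(coef(fit), coef(truth), tolerance = 1e-4)
})

test_that("generate-and-refit recovers random truths exactly (noiseless)", {
  set.seed(41)
  for (i in 1:30) {
    truth <- random_params()
    fit <- fit_full(noiseless_dataset(truth))
    expect_equal(coef(fit), coef(truth), tolerance = 1e-5)
  }
})

test_that("collinear low-dose points leave the saturation unidentifiable", {
  truth <- mean_curve()
  # m*D/ps < 0.01 for all points: pure linear regime
  d <- c(0.2, 0.5, 1.0) * 0.01 * truth$ps / truth$m
  ds <- calibration_dataset(d, pixel_from_dose(truth, d), background = truth$p0)
  expect_warning(fit <- fit_full(ds), "weakly identified")
  expect_true("ps_unidentifiable" %in% fit$flags)
})

test_that("Method I closed form is self-consistent at one and two points", {
  truth <- calibration_params(245, 3542, 31.28)
  one <- calibration_dataset(80, pixel_from_dose(truth, 80))
  f1 <- fit_method_I(one, universal_p0 = 245, universal_ps = 3542)
  expect_equal(f1$params$m, 31.28, tolerance = 1e-10)
  two <- calibration_dataset(c(40, 80), pixel_from_dose(truth, c(40, 80)))
  f2 <- fit_method_I(two, universal_p0 = 245, universal_ps = 3542)
  expect_equal(f2$params$m, f1$params$m, tolerance = 1e-6)
})

test_that("Method I rejects points at or outside the universal range", {
  d <- calibration_dataset(80, 245)  # pixel equal to universal background
  expect_error(fit_method_I(d, 245, 3542), class = "filmcal_infeasible_error")
  d2 <- calibration_dataset(80, 245 + 3542)
  expect_error(fit_method_I(d2, 245, 3542), class = "filmcal_infeasible_error")
})

test_that("Method II takes the background from the film and fits the slope", {
  truth <- calibration_params(240, 3542, 33.50)
  one <- calibration_dataset(80, pixel_from_dose(truth, 80), background = 240)
  f <- fit_method_II(one, universal_ps = 3542)
  expect_equal(f$params$p0, 240)
  expect_equal(f$params$m, 33.50, tolerance = 1e-10)
  two <- calibration_dataset(c(40, 80), pixel_from_dose(truth, c(40, 80)),
                             background = 240)
  expect_equal(fit_method_II(two, 3542)$params$m, 33.50, tolerance = 1e-6)
})

test_that("Method II fails when the background exceeds the exposed pixel", {
  d <- calibration_dataset(80, 300, background = 400)
  expect_error(fit_method_II(d, 3542), class = "filmcal_infeasible_error")
})

test_that("Method III two-point solver inverts the nonlinear system exactly", {
  truth <- calibration_params(254, 3209, 40.18)
  ds <- calibration_dataset(c(40, 120), pixel_from_dose(truth, c(40, 120)),
                            background = 254)
  fit <- fit_method_III(ds)
  expect_equal(coef(fit), coef(truth), tolerance = 1e-8)
})

test_that("Method III three-point least squares recovers random truths", {
  set.seed(42)
  for (i in 1:30) {
    truth <- random_params()
    d <- c(40, 80, 120)
    ds <- calibration_dataset(d, pixel_from_dose(truth, d), background = truth$p0)
    expect_equal(coef(fit_method_III(ds)), coef(truth), tolerance = 1e-5)
  }
})

test_that("Method III refuses degenerate two-point data", {
  # net pixel proportional to dose: no curvature information
  ds <- calibration_dataset(c(40, 120), c(254 + 400, 254 + 1200), background = 254)
  expect_error(fit_method_III(ds), class = "filmcal_unidentifiable_error")
  # super-linear growth: inconsistent with a saturating model
  ds2 <- calibration_dataset(c(40, 120), c(254 + 300, 254 + 1500), background = 254)
  expect_error(fit_method_III(ds2), class = "filmcal_infeasible_error")
  expect_error(calibration_dataset(c(40, 40), c(600, 700)),
               class = "filmcal_unidentifiable_error")
})

test_that("all strategies agree with the full fit on noiseless data", {
  truth <- mean_curve()
  full <- fit_full(noiseless_dataset(truth))
  one <- calibration_dataset(80, pixel_from_dose(truth, 80), background = truth$p0)
  two <- calibration_dataset(c(40, 120), pixel_from_dose(truth, c(40, 120)),
                             background = truth$p0)
  fI <- fit_method_I(one, truth$p0, truth$ps)
  fII <- fit_method_II(one, truth$ps)
  fIII <- fit_method_III(two)
  for (f in list(full, fI, fII, fIII)) {
    expect_equal(coef(f), coef(truth), tolerance = 1e-6)
  }
})

test_that("fit result is invariant to point ordering", {
  truth <- mean_curve()
  d <- c(16, 24, 32, 48, 64, 80, 96, 128)
  px <- pixel_from_dose(truth, d)
  perm <- c(5, 1, 8, 3, 7, 2, 6, 4)
  f1 <- fit_full(calibration_dataset(d, px, background = 245))
  f2 <- fit_full(calibration_dataset(d[perm], px[perm], background = 245))
  expect_identical(coef(f1), coef(f2))
})

test_that("two-step batch fit averages saturation over non-reference films", {
  truth <- mean_curve()
  # identical noiseless films: the optimum is the shared truth
  ds <- replicate(3, noiseless_dataset(truth), simplify = FALSE)
  res <- fit_batch_two_step(ds)
  expect_equal(res$optimal_ps, truth$ps, tolerance = 1e-6)
  expect_equal(res$fits[[1]]$params$m, truth$m, tolerance = 1e-6)

  # films with different ps: optimum is the mean of the free fits
  ps_vals <- 3271 * c(0.95, 1.00, 1.06)
  ds2 <- lapply(ps_vals, function(ps)
    noiseless_dataset(calibration_params(245, ps, 31.7)))
  res2 <- fit_batch_two_step(ds2)
  expect_equal(res2$optimal_ps, mean(ps_vals), tolerance = 1e-5)

  # a reference-flagged film is excluded from the average
  ref <- noiseless_dataset(calibration_params(245, 2000, 31.7), reference = TRUE)
  res3 <- fit_batch_two_step(c(ds2, list(ref)))
  expect_equal(res3$optimal_ps, mean(ps_vals), tolerance = 1e-5)
  expect_length(res3$fits, 4L)
})

test_that("fitting preconditions are enforced", {
  truth <- mean_curve()
  two <- calibration_dataset(c(40, 80), pixel_from_dose(truth, c(40, 80)))
  expect_error(fit_full(two, fix_p0 = FALSE), class = "filmcal_config_error")
  expect_error(fit_method_III(two), class = "filmcal_config_error")  # no background
  expect_error(fit_batch_two_step(list(noiseless_dataset(truth))),
               class = "filmcal_config_error")
})
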