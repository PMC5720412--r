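# Calibration transfer via parameter ratios, and the local-dose-error
# figure of merit.

test_that("saturation ratio is the mean-standard over reference quotient", {
  ref <- calibration_params(245, 3271, 31.7)
  expect_equal(compute_ps_ratio(ref, ref), 1.0)
  std <- list(calibration_params(245, 3500, 30), calibration_params(245, 3600, 30))
  expect_equal(compute_ps_ratio(std, ref), 3550 / 3271, tolerance = 1e-12)
  # the batch mean 3542.5 against the reference 3271 gives the 1.083 ratio
  std2 <- calibration_params(245, 3542.5, 30)
  expect_equal(round(compute_ps_ratio(std2, ref), 3), 1.083)
  expect_error(compute_ps_ratio(list(), ref), class = "filmcal_config_error")
})

test_that("slope ratio is a plain same-day quotient", {
  a <- calibration_params(240, 3577, 33.58)
  expect_equal(compute_m_ratio(a, a), 1.0)
  b <- calibration_params(247, 3585, 30.80)
  expect_equal(compute_m_ratio(b, a), 30.80 / 33.58, tolerance = 1e-12)
})

test_that("derive_curve scales saturation and slope, leaves background", {
  ref <- calibration_params(245, 3271, 31.7)
  geo <- irradiation_geometry(90, 20, 10)
  tab <- data.frame(field_cm = 20, depth_cm = 10, m_ratio = 1.05)
  rm1 <- ratio_model(1.083, tab, irradiation_geometry(95, 3, 5))
  out <- derive_curve(ref, rm1, geo)
  expect_equal(out$p0, 245)
  expect_equal(round(out$ps), 3542)  # 3271 * 1.083
  expect_equal(out$m, 31.7 * 1.05, tolerance = 1e-12)

  # unit ratios reproduce the reference
  rm_unit <- ratio_model(1, data.frame(field_cm = 20, depth_cm = 10, m_ratio = 1),
                         irradiation_geometry(95, 3, 5))
  expect_equal(coef(derive_curve(ref, rm_unit, geo)), coef(ref))
})

test_that("derive_curve round-trips through ratios measured from its output", {
  ref <- calibration_params(245, 3271, 31.7)
  geo <- irradiation_geometry(90, 10, 5)
  rm1 <- ratio_model(1.083, data.frame(field_cm = 10, depth_cm = 5, m_ratio = 1.03),
                     irradiation_geometry(95, 3, 5))
  derived <- derive_curve(ref, rm1, geo)
  ps_r <- compute_ps_ratio(derived, ref)
  m_r <- compute_m_ratio(derived, ref)
  back <- calibration_params(derived$p0, derived$ps / ps_r, derived$m / m_r)
  expect_equal(coef(back), coef(ref), tolerance = 1e-12)
})

test_that("geometry lookup is exact-key unless interpolation is enabled", {
  ref <- calibration_params(245, 3271, 31.7)
  tab <- data.frame(field_cm = c(20, 20), depth_cm = c(5, 10), m_ratio = c(1.02, 1.05))
  rm1 <- ratio_model(1.0, tab, irradiation_geometry(95, 3, 5))
  expect_error(derive_curve(ref, rm1, irradiation_geometry(90, 20, 7.5)),
               class = "filmcal_lookup_error")
  out <- derive_curve(ref, rm1, irradiation_geometry(90, 20, 7.5), interpolate = TRUE)
  expect_equal(out$m, 31.7 * 1.035, tolerance = 1e-12)
  expect_error(derive_curve(ref, rm1, irradiation_geometry(90, 5, 5)),
               class = "filmcal_lookup_error")
})

test_that("ratio model validates its table", {
  geo <- irradiation_geometry(95, 3, 5)
  expect_error(ratio_model(-1, data.frame(field_cm = 1, depth_cm = 1, m_ratio = 1), geo),
               class = "filmcal_domain_error")
  dup <- data.frame(field_cm = c(5, 5), depth_cm = c(1, 1), m_ratio = c(1, 1.01))
  expect_error(ratio_model(1, dup, geo), class = "filmcal_parse_error")
  odd <- data.frame(field_cm = 5, depth_cm = 1, m_ratio = 1.5)
  expect_warning(ratio_model(1, odd, geo), "band")
})

test_that("local dose error is zero for identical curves and matches arithmetic", {
  p <- mean_curve()
  lde <- local_dose_error(p, p)
  expect_lt(lde$max_abs_error, 1e-12)
  expect_true(all(abs(lde$table$rel_error) < 1e-12))
})

test_that("a pure slope perturbation gives a dose-independent error of -dm/(m+dm)", {
  p <- mean_curve()
  for (delta in c(-0.08, -0.02, 0.02, 0.08)) {
    test <- calibration_params(p$p0, p$ps, p$m * (1 + delta))
    lde <- local_dose_error(test, p, seq(10, 128, by = 2))
    expected <- 1 / (1 + delta) - 1
    expect_equal(lde$table$rel_error, rep(expected, nrow(lde$table)),
                 tolerance = 1e-12)
    # small-perturbation limit: within 15% of -delta
    expect_lt(abs(expected - (-delta)) / abs(delta), 0.15)
  }
})

test_that("a pure saturation perturbation grows in error magnitude with dose", {
  p <- mean_curve()
  for (delta in c(-0.05, 0.05)) {
    test <- calibration_params(p$p0, p$ps * (1 + delta), p$m)
    lde <- local_dose_error(test, p, seq(10, 128, by = 1))
    expect_true(all(diff(abs(lde$table$rel_error)) > 0))
  }
})

test_that("local dose error is antisymmetric to first order for small errors", {
  p <- mean_curve()
  test <- calibration_params(p$p0 * 1.002, p$ps * 1.01, p$m * 1.01)
  fwd <- local_dose_error(test, p)$table$rel_error
  bwd <- local_dose_error(p, test)$table$rel_error
  expect_equal(fwd, -bwd, tolerance = 0.05)
})

test_that("grid points outside the invertible range are excluded with a warning", {
  truth <- calibration_params(245, 5000, 31.7)
  test <- calibration_params(245, 2000, 31.7)  # saturates below the truth curve
  expect_warning(lde <- local_dose_error(test, truth, seq(10, 500, by = 10)),
                 "excluded")
  expect_gt(length(lde$excluded), 0)
  expect_false(any(is.na(lde$table$rel_error[!lde$table$dose %in% lde$excluded])))
})
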