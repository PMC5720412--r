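# Synthetic-data generator: parameter draws, noisy datasets, film images
# and ROI extraction, and the full pipeline closure.

test_that("parameter draws are deterministic and respect zero SDs", {
  cfg0 <- generator_config(inter_day_rel_sd = c(p0 = 0, ps = 0, m = 0))
  draws <- draw_day_params(cfg0, 5, seed = 1)
  for (d in draws) expect_equal(coef(d), coef(cfg0$mean_params))

  cfg <- generator_config()
  a <- draw_day_params(cfg, 10, seed = 7)
  b <- draw_day_params(cfg, 10, seed = 7)
  expect_identical(lapply(a, coef), lapply(b, coef))
  expect_false(identical(coef(a[[1]]), coef(draw_day_params(cfg, 1, seed = 8)[[1]])))
})

test_that("draw statistics reproduce the configured variation structure", {
  cfg <- generator_config()
  n <- 10000
  draws <- draw_day_params(cfg, n, seed = 99)
  mat <- t(vapply(draws, coef, numeric(3)))
  rel_sd <- apply(mat, 2, sd) / colMeans(mat)
  targets <- c(p0 = 0.018, ps = 0.057, m = 0.077)
  # sample SD of a normal: SE ~ sigma / sqrt(2n)
  for (par in names(targets)) {
    se <- targets[[par]] / sqrt(2 * n)
    expect_lt(abs(rel_sd[[par]] - targets[[par]]), 3 * se + 0.1 * targets[[par]] / sqrt(n))
  }
  # intra-day level: background held fixed, tighter slope variation
  intra <- draw_day_params(cfg, 2000, seed = 100, level = "intra")
  imat <- t(vapply(intra, coef, numeric(3)))
  expect_true(all(imat[, "p0"] == cfg$mean_params$p0))
  expect_lt(sd(imat[, "m"]) / mean(imat[, "m"]), 0.012)
})

test_that("zero-noise datasets close the generate-fit loop exactly", {
  truth <- mean_curve()
  ds <- generate_dataset(truth, readout_rel_noise = 0, seed = 1)
  expect_equal(ds$points$pixel, pixel_from_dose(truth, ds$points$dose))
  expect_equal(ds$background, truth$p0)
  fit <- fit_full(ds)
  expect_equal(coef(fit), coef(truth), tolerance = 1e-6)
})

test_that("1% readout noise yields ~1% slope scatter across replicates", {
  truth <- mean_curve()
  n_rep <- 300
  ms <- vapply(seq_len(n_rep), function(i) {
    ds <- generate_dataset(truth, readout_rel_noise = 0.01, seed = 2000 + i)
    fit_full(ds)$params$m
  }, numeric(1))
  rel_sd <- sd(ms) / mean(ms)
  expect_gt(rel_sd, 0.004)
  expect_lt(rel_sd, 0.02)
  # and the fitted slope is unbiased well below 0.5%
  expect_lt(abs(mean(ms) / truth$m - 1), 0.005)
})

test_that("film image geometry follows pitch and half-open pixel footprints", {
  truth <- mean_curve()
  img <- render_eightfield_image(truth, noise = 0, seed = 1)
  # 3 cm subfields at 0.123 mm pitch floor to 243 px; 1 cm gaps to 81 px
  expect_equal(dim(img$pixels), c(2 * 243 + 3 * 81, 4 * 243 + 5 * 81))
  expect_equal(nrow(img$layout), 8L)
  # subfield centre pixel carries the exact model value
  k <- 5
  ctr <- c(img$layout$center_row_mm[k], img$layout$center_col_mm[k])
  val <- extract_roi(img, ctr, 1.23)
  expect_equal(as.numeric(val), pixel_from_dose(truth, img$layout$dose[k]),
               tolerance = 1e-12)
  # ROI pixel counts at the default pitch: 1.23 mm -> 10x10, 12.3 mm -> 100x100
  expect_equal(attr(val, "n_pixels"), 100L)
  expect_equal(attr(extract_roi(img, ctr, 12.3), "n_pixels"), 10000L)
  expect_error(extract_roi(img, c(0.1, 0.1), 12.3), class = "filmcal_domain_error")
})

test_that("ROI mean is exact on constructed patterns", {
  flat <- film_image(matrix(7, 40, 40), pitch_mm = 0.123)
  expect_equal(as.numeric(extract_roi(flat, c(2.46, 2.46), 1.23)), 7)
  checker <- film_image(outer(1:40, 1:40, function(i, j) (i + j) %% 2 * 2),
                        pitch_mm = 0.123)
  expect_equal(as.numeric(extract_roi(checker, c(2.46, 2.46), 1.23)), 1.0)
})

test_that("full image pipeline recovers generating parameters", {
  truth <- calibration_params(250, 3400, 35)
  img <- render_eightfield_image(truth, noise = 0, seed = 1)
  ds <- image_to_dataset(img)
  expect_equal(ds$background, truth$p0, tolerance = 1e-12)
  fit <- fit_full(ds)
  expect_true(all(abs(coef(fit) / coef(truth) - 1) <= 1e-3))
})

test_that("inter-field cross-talk biases the fitted saturation low", {
  truth <- mean_curve()
  fit_ps <- function(ct) {
    img <- render_eightfield_image(truth, noise = 0, seed = 1, crosstalk = ct)
    fit_full(image_to_dataset(img))$params$ps
  }
  expect_lt(fit_ps(0.02), fit_ps(0))
  expect_equal(fit_ps(0), truth$ps, tolerance = 1e-3)
})

test_that("generator rejects implausible configurations", {
  expect_error(generator_config(readout_rel_noise = -0.1),
               class = "filmcal_config_error")
  expect_error(generator_config(dose_schedule = c(0, 50)),
               class = "filmcal_config_error")
  expect_error(generate_dataset(mean_curve(), dose_schedule = numeric(0)),
               class = "filmcal_config_error")
  expect_error(render_eightfield_image(mean_curve(), doses = c(10, 20)),
               class = "filmcal_config_error")
})
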