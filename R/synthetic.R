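# Synthetic data generation: parameter ensembles with realistic day-to-day
# variation, noisy calibration datasets, and rendered multi-field film
# images with ROI extraction. Everything is reproducible given a seed.

#' Generator configuration
#'
#' Defaults encode the variation structure observed for Kodak XV film over a
#' multi-year QA program: inter-day relative SDs of 1.8%/5.7%/7.7% for
#' (background, saturation, slope), intra-day SDs of 1.8%/0.8% for
#' (saturation, slope), mean curve (245, 3271, 31.7), ~1% scanner readout
#' noise, and an eight-dose schedule spanning 16-128 cGy.
#'
#' @param mean_params Mean [calibration_params()].
#' @param inter_day_rel_sd Named triple `c(p0=, ps=, m=)` of relative 1-sigma
#'   inter-day SDs.
#' @param intra_day_rel_sd Named pair `c(ps=, m=)` of relative intra-day SDs
#'   (the background is re-measured per film, so it carries no separate
#'   intra-day term).
#' @param readout_rel_noise Relative 1-sigma pixel readout noise.
#' @param dose_schedule Doses, cGy, each in (0, 200].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(mean_params = calibration_params(245, 3271, 31.7),
                             inter_day_rel_sd = c(p0 = 0.018, ps = 0.057, m = 0.077),
                             intra_day_rel_sd = c(ps = 0.018, m = 0.008),
                             readout_rel_noise = 0.01,
                             dose_schedule = c(16, 24, 32, 48, 64, 80, 96, 128)) {
  assert_params(mean_params)
  if (any(inter_day_rel_sd < 0) || any(intra_day_rel_sd < 0) || readout_rel_noise < 0) {
    abort_config("all relative SDs must be >= 0")
  }
  if (!all(c("p0", "ps", "m") %in% names(inter_day_rel_sd))) {
    abort_config("inter_day_rel_sd needs named components p0, ps, m")
  }
  if (!all(c("ps", "m") %in% names(intra_day_rel_sd))) {
    abort_config("intra_day_rel_sd needs named components ps, m")
  }
  if (any(dose_schedule <= 0) || any(dose_schedule > 200)) {
    abort_config("dose schedule must lie in (0, 200] cGy")
  }
  structure(list(mean_params = mean_params,
                 inter_day_rel_sd = inter_day_rel_sd[c("p0", "ps", "m")],
                 intra_day_rel_sd = intra_day_rel_sd[c("ps", "m")],
                 readout_rel_noise = readout_rel_noise,
                 dose_schedule = sort(dose_schedule)),
            class = "generator_config")
}

#' Draw per-day calibration parameters
#'
#' Each day's curve is the mean curve with independent Gaussian relative
#' perturbations at the configured inter-day (or intra-day) SDs. Draws that
#' violate parameter positivity are rejected and redrawn (the rejection
#' count is attached as an attribute); a configuration whose SDs reject more
#' than 10% of draws is refused.
#'
#' @param config A [generator_config()].
#' @param n_days Number of days to draw (>= 1).
#' @param seed RNG seed; same seed, same draws.
#' @param level `"inter"` (default) perturbs all three parameters at the
#'   inter-day SDs; `"intra"` perturbs only (ps, m) at the intra-day SDs.
#' @return List of [calibration_params()] of length `n_days`, with attribute
#'   `"rejected"`.
#' @export
draw_day_params <- function(config, n_days, seed = NULL,
                            level = c("inter", "intra")) {
  if (!inherits(config, "generator_config")) {
    abort_parse("config must be a 'generator_config'")
  }
  level <- match.arg(level)
  if (n_days < 1) abort_config("n_days must be >= 1")
  mp <- config$mean_params
  sds <- if (level == "inter") {
    config$inter_day_rel_sd
  } else {
    c(p0 = 0, config$intra_day_rel_sd)[c("p0", "ps", "m")]
  }
  with_seed(seed, {
    rejected <- 0L
    draws <- vector("list", n_days)
    for (i in seq_len(n_days)) {
      for (attempt in seq_len(100L)) {
        p0 <- mp$p0 * (1 + stats::rnorm(1, 0, sds[["p0"]]))
        ps <- mp$ps * (1 + stats::rnorm(1, 0, sds[["ps"]]))
        m <- mp$m * (1 + stats::rnorm(1, 0, sds[["m"]]))
        if (p0 >= 0 && ps > 0 && m > 0) break
        rejected <- rejected + 1L
      }
      if (p0 < 0 || ps <= 0 || m <= 0) {
        abort_config("could not draw valid parameters; SDs are too large")
      }
      draws[[i]] <- calibration_params(p0, ps, m)
    }
    if (rejected > 0.1 * n_days) {
      abort_config(sprintf(
        "%d of %d draws rejected (> 10%%): configured SDs are implausibly large",
        rejected, n_days))
    }
    attr(draws, "rejected") <- rejected
    draws
  })
}

#' Generate a noisy calibration dataset
#'
#' Evaluates the curve at the dose schedule and applies multiplicative
#' Gaussian readout noise to each exposed pixel and to the background film.
#' A noise realisation that breaks the pixel-increases-with-dose invariant
#' is discarded and regenerated (with a warning), up to 5 attempts.
#'
#' @param params True [calibration_params()] for the day.
#' @param dose_schedule Doses, cGy.
#' @param readout_rel_noise Relative 1-sigma pixel noise.
#' @param seed RNG seed.
#' @param geometry Optional [irradiation_geometry()] to attach.
#' @param ... Further arguments (`batch_id`, `day_id`, `reference`) passed to
#'   [calibration_dataset()].
#' @return A [calibration_dataset()].
#' @export
generate_dataset <- function(params, dose_schedule = c(16, 24, 32, 48, 64, 80, 96, 128),
                             readout_rel_noise = 0.01, seed = NULL,
                             geometry = NULL, ...) {
  assert_params(params)
  if (!length(dose_schedule)) abort_config("dose schedule must be non-empty")
  dose_schedule <- sort(dose_schedule)
  clean <- pixel_from_dose(params, dose_schedule)
  with_seed(seed, {
    for (attempt in seq_len(5L)) {
      pixel <- clean * (1 + stats::rnorm(length(clean), 0, readout_rel_noise))
      background <- params$p0 * (1 + stats::rnorm(1, 0, readout_rel_noise))
      if (!is.unsorted(pixel, strictly = TRUE) && all(pixel > 0) && background >= 0) {
        return(calibration_dataset(dose_schedule, pixel, background = background,
                                   geometry = geometry, ...))
      }
      warning("noise realisation broke pixel monotonicity; regenerating", call. = FALSE)
    }
    abort_config("could not generate a monotone dataset in 5 attempts; noise too large")
  })
}

# ---- film images ------------------------------------------------------------

#' Film image container
#'
#' A scanned (or synthesised) film as a 2-D pixel matrix with its physical
#' pixel pitch and, for multi-field calibration films, the subfield layout.
#' Coordinates are row-major with origin at the top-left corner; pixel
#' `[i, j]` covers the half-open square `[(i-1)p, ip) x [(j-1)p, jp)` mm,
#' so its centre sits at `((i-0.5)p, (j-0.5)p)`.
#'
#' @param pixels Numeric matrix of counts.
#' @param pitch_mm Physical pixel pitch, mm (> 0); the scanner default is
#'   0.123 mm.
#' @param layout Optional data frame of subfields: `row`, `col` (grid
#'   position), `dose` (cGy), `center_row_mm`, `center_col_mm`.
#' @param margin_mm Optional width of the unexposed border between the image
#'   edge and the first exposed region, mm (used for background ROIs).
#' @return An object of class `film_image`.
#' @export
film_image <- function(pixels, pitch_mm = 0.123, layout = NULL, margin_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_parse("pixels must be a numeric matrix")
  }
  if (pitch_mm <= 0) abort_domain("pixel pitch must be > 0")
  if (!is.null(layout)) {
    need <- c("row", "col", "dose", "center_row_mm", "center_col_mm")
    if (!is.data.frame(layout) || !all(need %in% names(layout))) {
      abort_parse("layout needs columns row, col, dose, center_row_mm, center_col_mm")
    }
    if (any(layout$center_row_mm <= 0 | layout$center_row_mm >= nrow(pixels) * pitch_mm) ||
        any(layout$center_col_mm <= 0 | layout$center_col_mm >= ncol(pixels) * pitch_mm)) {
      abort_domain("subfield layout extends outside the image")
    }
  }
  structure(list(pixels = pixels, pitch_mm = pitch_mm, layout = layout,
                 margin_mm = margin_mm),
            class = "film_image")
}

#' @export
print.film_image <- function(x, ...) {
  cat(sprintf("<film_image> %d x %d px @ %.3g mm (%.1f x %.1f mm)%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pitch_mm,
              nrow(x$pixels) * x$pitch_mm, ncol(x$pixels) * x$pitch_mm,
              if (!is.null(x$layout)) sprintf(", %d subfields", nrow(x$layout)) else ""))
  invisible(x)
}

#' Render a synthetic 8-field calibration film
#'
#' Synthesises the scan of a single film exposed with eight 3x3 cm^2
#' subfields at different doses, arranged on a 2x4 grid separated by 1-cm
#' unexposed gaps. Each subfield is filled with the model pixel value for
#' its dose, the rest of the film sits at the background, and multiplicative
#' Gaussian readout noise is applied per pixel.
#'
#' An optional cross-talk term emulates inter-field scatter: each subfield's
#' effective dose is increased by `crosstalk` times the summed dose of its
#' edge-adjacent neighbours. Because low-dose fields gain relatively more,
#' cross-talk bends the apparent curve toward earlier saturation and biases
#' a subsequent fit's saturation value low -- the mechanism that makes
#' multi-field reference films unsuitable for batch saturation averaging.
#'
#' @param params True [calibration_params()].
#' @param doses Eight subfield doses, cGy, assigned row-major.
#' @param noise Relative 1-sigma per-pixel readout noise.
#' @param seed RNG seed.
#' @param crosstalk Fraction of neighbouring subfield dose added (default 0).
#' @param pitch_mm Pixel pitch, mm.
#' @param subfield_cm,gap_cm Subfield edge and gap width, cm.
#' @return A [film_image()] with the subfield layout attached.
#' @export
render_eightfield_image <- function(params,
                                    doses = c(16, 24, 32, 48, 64, 80, 96, 128),
                                    noise = 0.01, seed = NULL, crosstalk = 0,
                                    pitch_mm = 0.123, subfield_cm = 3, gap_cm = 1) {
  assert_params(params)
  if (length(doses) != 8L) abort_config("an 8-field film needs exactly 8 doses")
  if (any(doses <= 0)) abort_domain("subfield doses must be positive")
  if (crosstalk < 0) abort_config("crosstalk fraction must be >= 0")

  sub_px <- floor(subfield_cm * 10 / pitch_mm)   # 3 cm at 0.123 mm -> 243 px
  gap_px <- floor(gap_cm * 10 / pitch_mm)
  n_row_grid <- 2L
  n_col_grid <- 4L
  nr <- n_row_grid * sub_px + (n_row_grid + 1L) * gap_px
  nc <- n_col_grid * sub_px + (n_col_grid + 1L) * gap_px

  dose_grid_mat <- matrix(doses, nrow = n_row_grid, ncol = n_col_grid, byrow = TRUE)
  eff <- dose_grid_mat
  if (crosstalk > 0) {
    for (r in seq_len(n_row_grid)) {
      for (cc in seq_len(n_col_grid)) {
        nb <- 0
        if (r > 1) nb <- nb + dose_grid_mat[r - 1, cc]
        if (r < n_row_grid) nb <- nb + dose_grid_mat[r + 1, cc]
        if (cc > 1) nb <- nb + dose_grid_mat[r, cc - 1]
        if (cc < n_col_grid) nb <- nb + dose_grid_mat[r, cc + 1]
        eff[r, cc] <- dose_grid_mat[r, cc] + crosstalk * nb
      }
    }
  }

  img <- matrix(params$p0, nrow = nr, ncol = nc)
  layout <- vector("list", 8L)
  k <- 0L
  for (r in seq_len(n_row_grid)) {
    for (cc in seq_len(n_col_grid)) {
      k <- k + 1L
      r0 <- gap_px + (r - 1L) * (sub_px + gap_px)
      c0 <- gap_px + (cc - 1L) * (sub_px + gap_px)
      img[(r0 + 1L):(r0 + sub_px), (c0 + 1L):(c0 + sub_px)] <-
        pixel_from_dose(params, eff[r, cc])
      layout[[k]] <- data.frame(
        row = r, col = cc, dose = dose_grid_mat[r, cc],
        center_row_mm = (r0 + sub_px / 2) * pitch_mm,
        center_col_mm = (c0 + sub_px / 2) * pitch_mm)
    }
  }
  if (noise > 0) {
    img <- with_seed(seed, {
      img * (1 + matrix(stats::rnorm(length(img), 0, noise), nrow = nr))
    })
  }
  film_image(img, pitch_mm, do.call(rbind, layout), margin_mm = gap_px * pitch_mm)
}

#' Mean pixel value in a square region of interest
#'
#' Averages the pixels whose centres fall inside the half-open square ROI
#' `[center - size/2, center + size/2)` in each axis. At the default 0.123
#' mm pitch a 1.23 mm ROI covers exactly 10x10 pixels and a 12.3 mm ROI
#' 100x100, independent of alignment.
#'
#' @param image A [film_image()].
#' @param center Numeric `(row_mm, col_mm)` of the ROI centre.
#' @param size_mm ROI edge, mm.
#' @return Mean pixel value (scalar) with attribute `n_pixels`.
#' @export
extract_roi <- function(image, center, size_mm) {
  if (!inherits(image, "film_image")) abort_parse("image must be a 'film_image'")
  if (length(center) != 2L || size_mm <= 0) {
    abort_parse("center must be (row_mm, col_mm) and size_mm > 0")
  }
  p <- image$pitch_mm
  lo <- center - size_mm / 2
  hi <- center + size_mm / 2
  if (lo[1] < 0 || lo[2] < 0 ||
      hi[1] > nrow(image$pixels) * p || hi[2] > ncol(image$pixels) * p) {
    abort_domain("ROI extends outside the image")
  }
  rc <- (seq_len(nrow(image$pixels)) - 0.5) * p
  cc <- (seq_len(ncol(image$pixels)) - 0.5) * p
  # half-open [lo, hi): an epsilon guards against losing an exact-boundary
  # pixel centre to floating-point rounding
  eps <- 1e-9 * size_mm
  rows <- which(rc >= lo[1] - eps & rc < hi[1] - eps)
  cols <- which(cc >= lo[2] - eps & cc < hi[2] - eps)
  if (!length(rows) || !length(cols)) abort_domain("ROI contains no pixel centres")
  block <- image$pixels[rows, cols, drop = FALSE]
  structure(mean(block), n_pixels = length(block))
}

#' Extract a calibration dataset from a multi-field film image
#'
#' Applies [extract_roi()] at every subfield centre of the image's layout
#' (1.23 mm ROI by default, matching the exposed-film convention) and, if
#' requested, a background ROI centred in the top-left gap.
#'
#' @param image A [film_image()] with a layout.
#' @param roi_mm ROI edge for subfields, mm.
#' @param background Take a background ROI from the unexposed border
#'   (12.3 mm, the unexposed-film convention) and attach it to the dataset.
#' @param ... Passed to [calibration_dataset()].
#' @return A [calibration_dataset()].
#' @export
image_to_dataset <- function(image, roi_mm = 1.23, background = TRUE, ...) {
  if (!inherits(image, "film_image")) abort_parse("image must be a 'film_image'")
  if (is.null(image$layout)) abort_config("image has no subfield layout")
  pix <- vapply(seq_len(nrow(image$layout)), function(k) {
    as.numeric(extract_roi(
      image, c(image$layout$center_row_mm[k], image$layout$center_col_mm[k]), roi_mm))
  }, numeric(1))
  bg <- NULL
  if (background) {
    # Background ROI in the unexposed top-left border. Cap the ROI at the
    # 12.3 mm unexposed-film convention, shrinking to fit narrow borders.
    if (is.null(image$margin_mm)) {
      abort_config("image does not record an unexposed border; cannot take a background ROI")
    }
    bg_size <- min(12.3, image$margin_mm - 2 * image$pitch_mm)
    if (bg_size <= image$pitch_mm) {
      abort_config("unexposed border too narrow for a background ROI")
    }
    bg <- as.numeric(extract_roi(image, rep(image$margin_mm / 2, 2), bg_size))
  }
  calibration_dataset(image$layout$dose, pix, background = bg, ...)
}
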