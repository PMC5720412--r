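# Calibration transfer between irradiation geometries.
#
# The sensitivity slope factorizes as m = mE(energy, field size, depth) x
# mFP(processing). Taking same-day ratios to a fixed reference geometry
# cancels the processing factor, so the slope ratio is a stable property of
# the geometry pair; together with the saturation ratio between the standard
# (single-field) and multi-field reference methods it lets one reference
# curve generate curves for other geometries.

#' Ratio model for calibration-curve transfer
#'
#' @param ps_ratio Saturation ratio, mean standard-method `ps` over the
#'   multi-field reference `ps` (> 0).
#' @param m_ratio_table Data frame with columns `field_cm`, `depth_cm`,
#'   `m_ratio`: the slope ratio of each target geometry to the reference.
#'   Keys must be unique; ratios positive.
#' @param reference_geometry The [irradiation_geometry()] of the reference
#'   curve.
#' @param validate Run plausibility checks on the table (warn if ratios lie
#'   outside the empirically observed 0.99-1.05 band; warnings only, since
#'   other scanners/films may differ).
#' @return An object of class `ratio_model`.
#' @export
ratio_model <- function(ps_ratio, m_ratio_table, reference_geometry,
                        validate = TRUE) {
  if (!is.numeric(ps_ratio) || length(ps_ratio) != 1L || ps_ratio <= 0) {
    abort_domain("ps_ratio must be a positive scalar")
  }
  need <- c("field_cm", "depth_cm", "m_ratio")
  if (!is.data.frame(m_ratio_table) || !all(need %in% names(m_ratio_table))) {
    abort_parse("m_ratio_table needs columns field_cm, depth_cm, m_ratio")
  }
  if (any(m_ratio_table$m_ratio <= 0)) abort_domain("all m ratios must be > 0")
  if (anyDuplicated(m_ratio_table[, c("field_cm", "depth_cm")])) {
    abort_parse("(field_cm, depth_cm) keys must be unique")
  }
  if (!inherits(reference_geometry, "irradiation_geometry")) {
    abort_parse("reference_geometry must be an 'irradiation_geometry'")
  }
  if (validate && any(m_ratio_table$m_ratio < 0.95 | m_ratio_table$m_ratio > 1.10)) {
    warning("m ratios outside the empirically observed ~0.99-1.05 band; check inputs",
            call. = FALSE)
  }
  structure(list(ps_ratio = as.numeric(ps_ratio),
                 m_ratio_table = m_ratio_table[need],
                 reference_geometry = reference_geometry),
            class = "ratio_model")
}

#' @export
print.ratio_model <- function(x, ...) {
  cat(sprintf("<ratio_model> ps_ratio = %.4g, %d geometry entr%s\n",
              x$ps_ratio, nrow(x$m_ratio_table),
              if (nrow(x$m_ratio_table) == 1) "y" else "ies"))
  invisible(x)
}

#' Saturation ratio between standard and reference methods
#'
#' Mean saturation pixel value of the standard (one-field-per-film) curves
#' divided by the multi-field reference curve's saturation.
#'
#' @param standard_params A [calibration_params()] or list of them, from
#'   standard-method fits.
#' @param reference_params The multi-field reference [calibration_params()].
#' @return Dimensionless ratio.
#' @examples
#' compute_ps_ratio(list(calibration_params(245, 3500, 30),
#'                       calibration_params(245, 3600, 30)),
#'                  calibration_params(245, 3271, 31.7))
#' @export
compute_ps_ratio <- function(standard_params, reference_params) {
  if (is_calibration_params(standard_params)) standard_params <- list(standard_params)
  if (!length(standard_params)) abort_config("need at least one standard parameter set")
  lapply(standard_params, assert_params)
  assert_params(reference_params)
  mean(vapply(standard_params, function(p) p$ps, numeric(1))) / reference_params$ps
}

#' Slope ratio between two same-day curves
#'
#' Dividing slopes measured on the same processing day cancels the
#' film-processing factor, isolating the energy/geometry dependence. The
#' caller is responsible for pairing same-day fits.
#'
#' @param standard_params,reference_params [calibration_params()] fitted on
#'   the same day.
#' @return Dimensionless ratio `m_standard / m_reference`.
#' @export
compute_m_ratio <- function(standard_params, reference_params) {
  assert_params(standard_params)
  assert_params(reference_params)
  standard_params$m / reference_params$m
}

#' Derive a calibration curve for a target geometry
#'
#' Scales a reference curve's saturation by the model's `ps_ratio` and its
#' slope by the tabulated slope ratio of the target geometry; the background
#' is geometry-independent and passes through unchanged.
#'
#' Lookup is by exact `(field_size, depth)` key. No interpolation is done
#' unless `interpolate = TRUE`, which enables linear interpolation in depth
#' at an exactly matching field size.
#'
#' @param reference Reference [calibration_params()].
#' @param ratios A [ratio_model()].
#' @param target Target [irradiation_geometry()].
#' @param interpolate Allow linear-in-depth interpolation at matching field
#'   size (default off).
#' @return Derived [calibration_params()] for the target geometry.
#' @export
derive_curve <- function(reference, ratios, target, interpolate = FALSE) {
  assert_params(reference)
  if (!inherits(ratios, "ratio_model")) abort_parse("ratios must be a 'ratio_model'")
  if (!inherits(target, "irradiation_geometry")) {
    abort_parse("target must be an 'irradiation_geometry'")
  }
  tab <- ratios$m_ratio_table
  hit <- tab$field_cm == target$field_size & tab$depth_cm == target$depth
  if (any(hit)) {
    m_ratio <- tab$m_ratio[which(hit)[1]]
  } else if (interpolate) {
    sub <- tab[tab$field_cm == target$field_size, , drop = FALSE]
    if (nrow(sub) < 2L || target$depth < min(sub$depth_cm) ||
        target$depth > max(sub$depth_cm)) {
      abort_lookup(sprintf(
        "cannot interpolate slope ratio for field %g cm, depth %g cm",
        target$field_size, target$depth))
    }
    sub <- sub[order(sub$depth_cm), ]
    m_ratio <- stats::approx(sub$depth_cm, sub$m_ratio, xout = target$depth)$y
  } else {
    abort_lookup(sprintf(
      "no slope ratio tabulated for field %g cm, depth %g cm (interpolation disabled)",
      target$field_size, target$depth))
  }
  calibration_params(reference$p0, reference$ps * ratios$ps_ratio,
                     reference$m * m_ratio)
}

#' Local dose error between two calibration curves
#'
#' The local dose error at dose D is the relative dose difference obtained
#' when a pixel value produced by the `truth` curve is inverted through the
#' `test` curve: \eqn{e(D) = (D_{test}(P_{truth}(D)) - D)/D}. It is the
#' figure of merit for judging whether a reduced-point or transferred curve
#' can replace a fully measured one.
#'
#' Grid doses whose truth pixel falls outside the test curve's invertible
#' range are flagged, excluded from the maximum, and reported with a
#' warning.
#'
#' @param test Candidate [calibration_params()] (or a `calibration_fit`).
#' @param truth Ground-truth [calibration_params()] (or a `calibration_fit`).
#' @param dose_grid Doses in cGy at which to evaluate; default 1-cGy steps
#'   over 10-150 cGy, the range over which film dosimetry is typically
#'   judged (below ~10 cGy the response is background-dominated and relative
#'   errors blow up while absolute errors stay within ~0.1 cGy).
#' @return A list of class `local_dose_error`: `table` (dose, pixel,
#'   estimated dose, relative error), `max_abs_error`, and `excluded` doses.
#' @examples
#' truth <- calibration_params(247, 3585, 30.80)
#' test <- calibration_params(245, 3542, 31.28)
#' local_dose_error(test, truth)$max_abs_error
#' @export
local_dose_error <- function(test, truth, dose_grid = seq(10, 150, by = 1)) {
  if (inherits(test, "calibration_fit")) test <- test$params
  if (inherits(truth, "calibration_fit")) truth <- truth$params
  assert_params(test)
  assert_params(truth)
  if (any(dose_grid <= 0)) abort_domain("dose grid must be strictly positive")
  pixel <- pixel_from_dose(truth, dose_grid)
  est <- dose_from_pixel_or_na(test, pixel)
  rel <- (est - dose_grid) / dose_grid
  excluded <- dose_grid[is.na(est)]
  if (length(excluded)) {
    warning(sprintf(
      "%d grid dose(s) outside the test curve's invertible range were excluded",
      length(excluded)), call. = FALSE)
  }
  structure(
    list(table = data.frame(dose = dose_grid, pixel = pixel,
                            dose_est = est, rel_error = rel),
         max_abs_error = if (all(is.na(rel))) NA_real_ else max(abs(rel), na.rm = TRUE),
         excluded = excluded),
    class = "local_dose_error"
  )
}

#' @export
print.local_dose_error <- function(x, ...) {
  cat(sprintf("<local_dose_error> %d doses, max |error| = %.3g%%%s\n",
              nrow(x$table), 100 * x$max_abs_error,
              if (length(x$excluded)) sprintf(" (%d excluded)", length(x$excluded)) else ""))
  invisible(x)
}
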