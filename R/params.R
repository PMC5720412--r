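#' Calibration curve parameters
#'
#' Bundle the three parameters of the single-target single-hit film response
#' curve in pixel-value form, \eqn{P(D) = P_0 + P_s (1 - e^{-mD/P_s})}.
#'
#' Convention: `ps` is the saturation pixel value *above background* (the
#' net pixel value the curve approaches at large dose), so the total pixel
#' value saturates at `p0 + ps`. All pixel values are real-valued ROI
#' averages, not integer scanner counts.
#'
#' @param p0 Background pixel value of unexposed film (fog plus base layer),
#'   in scanner counts. Must be finite and non-negative.
#' @param ps Saturation (net) pixel value, counts. Must be finite and positive.
#' @param m Sensitivity slope, the initial slope of the response curve, in
#'   counts per cGy. Must be finite and positive.
#' @return An object of class `calibration_params`.
#' @examples
#' calibration_params(245, 3271, 31.7)
#' @export
calibration_params <- function(p0, ps, m) {
  for (v in list(p0 = p0, ps = ps, m = m)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort_domain("calibration parameters must be finite numeric scalars")
    }
  }
  if (p0 < 0) abort_domain("background pixel value p0 must be >= 0")
  if (ps <= 0) abort_domain("saturation pixel value ps must be > 0")
  if (m <= 0) abort_domain("sensitivity slope m must be > 0")
  structure(list(p0 = as.numeric(p0), ps = as.numeric(ps), m = as.numeric(m)),
            class = "calibration_params")
}

is_calibration_params <- function(x) inherits(x, "calibration_params")

assert_params <- function(x) {
  if (!is_calibration_params(x)) {
    abort_domain("expected a 'calibration_params' object; see calibration_params()")
  }
  invisible(x)
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "<calibration_params>  P0 = %.4g  Ps = %.5g  m = %.4g counts/cGy  (saturates at %.5g)\n",
    x$p0, x$ps, x$m, x$p0 + x$ps
  ))
  invisible(x)
}

#' @export
coef.calibration_params <- function(object, ...) {
  c(p0 = object$p0, ps = object$ps, m = object$m)
}

#' Irradiation geometry metadata
#'
#' Describes the beam setup a calibration film was exposed under. The beam
#' energy is carried as a free-text label (the response model itself is
#' energy-agnostic; energy enters only through the sensitivity-slope ratio
#' between geometries).
#'
#' @param ssd Source-to-surface distance, cm (> 0).
#' @param field_size Side of the square field, cm (> 0).
#' @param depth Depth in phantom, cm (> 0).
#' @param energy Beam quality label, default `"6 MV"`.
#' @return An object of class `irradiation_geometry`.
#' @examples
#' irradiation_geometry(ssd = 95, field_size = 10, depth = 5)
#' @export
irradiation_geometry <- function(ssd, field_size, depth, energy = "6 MV") {
  for (v in list(ssd = ssd, field_size = field_size, depth = depth)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort_domain("ssd, field_size and depth must be positive finite scalars")
    }
  }
  structure(list(ssd = as.numeric(ssd), field_size = as.numeric(field_size),
                 depth = as.numeric(depth), energy = as.character(energy)),
            class = "irradiation_geometry")
}

#' @export
print.irradiation_geometry <- function(x, ...) {
  cat(sprintf("<irradiation_geometry> %s, SSD %g cm, %gx%g cm^2, depth %g cm\n",
              x$energy, x$ssd, x$field_size, x$field_size, x$depth))
  invisible(x)
}
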