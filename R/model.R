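#' Forward film response: pixel value from dose
#'
#' Evaluates the single-target single-hit response curve in pixel-value form,
#' \deqn{P(D) = P_0 + P_s \left(1 - e^{-mD/P_s}\right).}
#' The curve rises with initial slope `m` from the background `p0` and
#' saturates at `p0 + ps`.
#'
#' @param params A [calibration_params()] object.
#' @param dose Dose in cGy; vectorised, each element must be >= 0.
#' @return Pixel value(s), same length as `dose`.
#' @examples
#' p <- calibration_params(245, 3271, 31.7)
#' pixel_from_dose(p, c(0, 64, 128))
#' @seealso [dose_from_pixel()] for the inverse.
#' @export
pixel_from_dose <- function(params, dose) {
  assert_params(params)
  if (!is.numeric(dose) || any(!is.finite(dose))) {
    abort_domain("dose must be finite numeric")
  }
  if (any(dose < 0)) abort_domain("dose must be >= 0 cGy")
  params$p0 + params$ps * (1 - exp(-params$m * dose / params$ps))
}

#' Invert pixel value to dose
#'
#' Algebraic inverse of [pixel_from_dose()]:
#' \deqn{D = -\frac{P_s}{m}\,\ln\!\left(1 - \frac{P - P_0}{P_s}\right).}
#'
#' The inversion is only defined for pixel values between the background and
#' saturation. Pixels below `p0` raise a below-background error; pixels at or
#' within a relative `1e-9` of saturation (`p0 + ps`) raise a saturation
#' error rather than returning an arbitrarily large dose, because the
#' near-saturation regime is outside the model's validity.
#'
#' @param params A [calibration_params()] object.
#' @param pixel Pixel value(s), counts; vectorised.
#' @return Dose(s) in cGy.
#' @examples
#' p <- calibration_params(245, 3271, 31.7)
#' dose_from_pixel(p, pixel_from_dose(p, 80))
#' @export
dose_from_pixel <- function(params, pixel) {
  assert_params(params)
  if (!is.numeric(pixel) || any(!is.finite(pixel))) {
    abort_domain("pixel must be finite numeric")
  }
  if (any(pixel < params$p0)) {
    abort_below_background(sprintf(
      "pixel value below background (min %.6g < P0 = %.6g): dose undefined",
      min(pixel), params$p0))
  }
  frac <- (pixel - params$p0) / params$ps
  if (any(frac >= 1 - 1e-9)) {
    abort_saturation(sprintf(
      "pixel value at or beyond saturation (P0 + Ps = %.6g): dose undefined",
      params$p0 + params$ps))
  }
  -(params$ps / params$m) * log(1 - frac)
}

# Vectorised inversion that returns NA outside the invertible range instead
# of signalling; used where out-of-range points are flagged, not fatal.
dose_from_pixel_or_na <- function(params, pixel) {
  frac <- (pixel - params$p0) / params$ps
  ok <- is.finite(pixel) & pixel >= params$p0 & frac < 1 - 1e-9
  out <- rep(NA_real_, length(pixel))
  out[ok] <- -(params$ps / params$m) * log(1 - frac[ok])
  out
}

#' Initial slope of the response curve
#'
#' The sensitivity slope `m` is the derivative dP/dD of the response curve at
#' zero dose; this accessor exists so that code reads as the physics does.
#'
#' @param params A [calibration_params()] object.
#' @return The initial slope in counts per cGy (identically `params$m`).
#' @export
initial_slope <- function(params) {
  assert_params(params)
  params$m
}
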