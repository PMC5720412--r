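#' Measured calibration dataset
#'
#' One film-calibration measurement: (dose, pixel) points, an optional
#' background (unexposed film) pixel value, the irradiation geometry, and
#' batch/day labels. Points are stored sorted by dose, so fits are invariant
#' to input order.
#'
#' @param dose Doses in cGy; strictly positive, distinct.
#' @param pixel Pixel values (ROI averages), same length as `dose`; must
#'   increase with dose.
#' @param background Pixel value of an unexposed film from the same batch,
#'   or `NULL` when no background film is available.
#' @param geometry Optional [irradiation_geometry()].
#' @param batch_id,day_id Free-text labels grouping films by emulsion batch
#'   and processing day.
#' @param reference Logical; marks a multi-field reference film whose fitted
#'   saturation value is excluded from batch-level saturation averaging (its
#'   curvature is systematically shifted by inter-field scatter cross-talk).
#' @return An object of class `calibration_dataset`.
#' @examples
#' truth <- calibration_params(245, 3271, 31.7)
#' calibration_dataset(c(16, 64, 128), pixel_from_dose(truth, c(16, 64, 128)),
#'                     background = 245)
#' @export
calibration_dataset <- function(dose, pixel, background = NULL, geometry = NULL,
                                batch_id = NA_character_, day_id = NA_character_,
                                reference = FALSE) {
  if (!is.numeric(dose) || !is.numeric(pixel) || length(dose) != length(pixel)) {
    abort_parse("dose and pixel must be numeric vectors of equal length")
  }
  if (length(dose) < 1L) abort_parse("at least one (dose, pixel) point is required")
  if (any(!is.finite(dose)) || any(!is.finite(pixel))) {
    abort_parse("dose and pixel values must be finite")
  }
  if (any(dose <= 0)) abort_domain("calibration doses must be strictly positive")
  if (anyDuplicated(dose)) abort_unidentifiable("calibration doses must be distinct")
  ord <- order(dose)
  dose <- dose[ord]
  pixel <- pixel[ord]
  if (is.unsorted(pixel, strictly = TRUE)) {
    abort_domain("pixel values must increase strictly with dose")
  }
  if (!is.null(background)) {
    if (!is.numeric(background) || length(background) != 1L || !is.finite(background) ||
        background < 0) {
      abort_parse("background must be a single non-negative pixel value")
    }
    background <- as.numeric(background)
  }
  if (!is.null(geometry) && !inherits(geometry, "irradiation_geometry")) {
    abort_parse("geometry must be an 'irradiation_geometry' object")
  }
  structure(
    list(points = data.frame(dose = as.numeric(dose), pixel = as.numeric(pixel)),
         background = background, geometry = geometry,
         batch_id = as.character(batch_id), day_id = as.character(day_id),
         reference = isTRUE(reference)),
    class = "calibration_dataset"
  )
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("<calibration_dataset> %d point(s), dose %g-%g cGy%s%s%s\n",
              nrow(x$points), min(x$points$dose), max(x$points$dose),
              if (!is.null(x$background)) sprintf(", background %.4g", x$background) else "",
              if (!is.na(x$batch_id)) sprintf(", batch %s", x$batch_id) else "",
              if (x$reference) " [reference film]" else ""))
  print(x$points, row.names = FALSE)
  invisible(x)
}

n_points <- function(data) nrow(data$points)

assert_dataset <- function(data) {
  if (!inherits(data, "calibration_dataset")) {
    abort_parse("expected a 'calibration_dataset'; see calibration_dataset()")
  }
  invisible(data)
}
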