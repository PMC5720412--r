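# Readers and writers. JSON is the canonical parameter interchange (nested
# metadata travels with the numbers); CSV is used only for flat point and
# ensemble tables; TIFF (16-bit, with a JSON sidecar for physical metadata)
# for film images. Doses are cGy everywhere; no unit conversion layer.

#' @importFrom jsonlite read_json write_json
#' @importFrom utils read.csv write.csv head
NULL

geometry_to_list <- function(g) {
  if (is.null(g)) return(NULL)
  list(ssd_cm = g$ssd, field_cm = g$field_size, depth_cm = g$depth, energy = g$energy)
}

geometry_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  need <- c("ssd_cm", "field_cm", "depth_cm")
  if (!all(need %in% names(x))) {
    abort_parse("geometry needs fields ssd_cm, field_cm, depth_cm")
  }
  irradiation_geometry(x$ssd_cm, x$field_cm, x$depth_cm,
                       energy = if (is.null(x$energy)) "6 MV" else x$energy)
}

#' Read calibration points from CSV
#'
#' Expects one row per point with columns `dose_cGy` and `pixel`.
#'
#' @param path CSV file path.
#' @param ... Extra arguments (background, geometry, labels) passed to
#'   [calibration_dataset()].
#' @return A [calibration_dataset()].
#' @export
read_points_csv <- function(path, ...) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("dose_cGy", "pixel") %in% names(df))) {
    abort_parse(sprintf("%s: expected columns 'dose_cGy' and 'pixel', got: %s",
                        path, paste(names(df), collapse = ", ")))
  }
  calibration_dataset(df$dose_cGy, df$pixel, ...)
}

#' Write calibration points to CSV
#' @param data A [calibration_dataset()].
#' @param path Output CSV path.
#' @export
write_points_csv <- function(data, path) {
  assert_dataset(data)
  df <- data.frame(dose_cGy = data$points$dose, pixel = data$points$pixel)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration dataset from JSON
#'
#' Format: `{"points": [{"dose_cGy":, "pixel":}, ...], "background":,
#' "geometry": {"ssd_cm":, "field_cm":, "depth_cm":}, "batch_id":,
#' "day_id":, "reference":}`. Only `points` is mandatory.
#'
#' @param path JSON file path.
#' @return A [calibration_dataset()].
#' @export
read_dataset_json <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$points) || !all(c("dose_cGy", "pixel") %in% names(x$points))) {
    abort_parse(sprintf("%s: 'points' must have fields dose_cGy and pixel", path))
  }
  calibration_dataset(
    x$points$dose_cGy, x$points$pixel,
    background = x$background,
    geometry = geometry_from_list(x$geometry),
    batch_id = if (is.null(x$batch_id)) NA_character_ else x$batch_id,
    day_id = if (is.null(x$day_id)) NA_character_ else x$day_id,
    reference = isTRUE(x$reference))
}

#' Write a calibration dataset to JSON
#' @param data A [calibration_dataset()].
#' @param path Output path.
#' @export
write_dataset_json <- function(data, path) {
  assert_dataset(data)
  x <- list(points = data.frame(dose_cGy = data$points$dose, pixel = data$points$pixel))
  if (!is.null(data$background)) x$background <- data$background
  if (!is.null(data$geometry)) x$geometry <- geometry_to_list(data$geometry)
  if (!is.na(data$batch_id)) x$batch_id <- data$batch_id
  if (!is.na(data$day_id)) x$day_id <- data$day_id
  if (data$reference) x$reference <- TRUE
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write fitted parameters to JSON
#'
#' Format: `{"P0":, "Ps":, "m":, "method":, "rms":}` (method and rms only
#' present for fits).
#'
#' @param x A `calibration_fit` or [calibration_params()].
#' @param path Output path.
#' @export
write_params_json <- function(x, path) {
  if (inherits(x, "calibration_fit")) {
    out <- list(P0 = x$params$p0, Ps = x$params$ps, m = x$params$m,
                method = x$method, rms = x$rms)
  } else {
    assert_params(x)
    out <- list(P0 = x$p0, Ps = x$ps, m = x$m)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read calibration parameters from JSON
#' @param path JSON with fields `P0`, `Ps`, `m`.
#' @return A [calibration_params()].
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("P0", "Ps", "m") %in% names(x))) {
    abort_parse(sprintf("%s: expected fields P0, Ps, m", path))
  }
  calibration_params(x$P0, x$Ps, x$m)
}

#' Read/write a ratio model as JSON
#'
#' Format: `{"ps_ratio":, "reference": {"ssd_cm":, "field_cm":, "depth_cm":},
#' "table": [{"field_cm":, "depth_cm":, "m_ratio":}, ...]}`.
#'
#' @param path File path.
#' @return `read_ratio_model_json()` returns a [ratio_model()].
#' @export
read_ratio_model_json <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$ps_ratio) || is.null(x$table) || is.null(x$reference)) {
    abort_parse(sprintf("%s: expected fields ps_ratio, reference, table", path))
  }
  ratio_model(x$ps_ratio, as.data.frame(x$table), geometry_from_list(x$reference))
}

#' @rdname read_ratio_model_json
#' @param model A [ratio_model()].
#' @export
write_ratio_model_json <- function(model, path) {
  if (!inherits(model, "ratio_model")) abort_parse("model must be a 'ratio_model'")
  jsonlite::write_json(
    list(ps_ratio = model$ps_ratio,
         reference = geometry_to_list(model$reference_geometry),
         table = model$m_ratio_table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a parameter ensemble from CSV
#'
#' Expects columns `day_id`, `batch_id`, `P0`, `Ps`, `m`.
#'
#' @param path CSV file path.
#' @return A [parameter_ensemble()].
#' @export
read_ensemble_csv <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("day_id", "batch_id", "P0", "Ps", "m")
  if (!all(need %in% names(df))) {
    abort_parse(sprintf("%s: expected columns %s", path, paste(need, collapse = ", ")))
  }
  parameter_ensemble(data.frame(p0 = df$P0, ps = df$Ps, m = df$m,
                                day_id = df$day_id, batch_id = df$batch_id))
}

#' Read an uncertainty budget from JSON
#'
#' Fields `ps`, `m`, `p`, `p0` as fractional relative 1-sigma values
#' (e.g. 0.01 for 1%); missing fields default to 0.
#'
#' @param path JSON file path.
#' @return An [uncertainty_budget()].
#' @export
read_budget_json <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  grab <- function(f) if (is.null(x[[f]])) 0 else x[[f]]
  uncertainty_budget(ps = grab("ps"), m = grab("m"), p = grab("p"), p0 = grab("p0"))
}

# ---- film images ------------------------------------------------------------

#' Write a film image as 16-bit TIFF plus JSON sidecar
#'
#' Pixel counts are stored as 16-bit grey values (counts / 65535). The TIFF
#' container carries no physical metadata, so the pixel pitch, unexposed
#' border and subfield layout are written to `<path>.json` alongside.
#'
#' @param image A [film_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_film_tiff <- function(image, path) {
  if (!inherits(image, "film_image")) abort_parse("image must be a 'film_image'")
  scaled <- pmin(pmax(image$pixels / 65535, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pitch_mm = image$pitch_mm, scale = 65535)
  if (!is.null(image$margin_mm)) meta$margin_mm <- image$margin_mm
  if (!is.null(image$layout)) meta$layout <- image$layout
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a film image written by [write_film_tiff()]
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return A [film_image()].
#' @export
read_film_tiff <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) abort_parse(sprintf("metadata sidecar not found: %s", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  film_image(m, pitch_mm = meta$pitch_mm,
             layout = if (is.null(meta$layout)) NULL else as.data.frame(meta$layout),
             margin_mm = meta$margin_mm)
}

# ---- bundled reference fixture ----------------------------------------------

#' Bundled reference parameter sets for three irradiation geometries
#'
#' Calibration parameters measured for Kodak XV film under three irradiation
#' geometries, each fitted with one background film plus eight dose points
#' (the per-geometry ground truth) and with every reduced-point strategy
#' (Methods Ia/Ib, IIa/IIb, IIIa/IIIb), together with the universal
#' background and saturation values used by Methods I and II. Geometry 3
#' comes from a film batch whose saturation value sits ~9% below the
#' universal value, which is what makes it the stress case for the
#' universal-saturation methods.
#'
#' @return A list with elements `universal` (`p0`, `ps`) and `geometries`,
#'   each geometry holding `geometry` ([irradiation_geometry()]), `full`
#'   (the eight-point [calibration_params()]) and `methods` (named list of
#'   [calibration_params()]).
#' @export
reference_geometries <- function() {
  path <- system.file("extdata", "reference_geometries.json", package = "filmcal",
                      mustWork = TRUE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  geoms <- lapply(x$geometries, function(g) {
    list(
      geometry = geometry_from_list(g$geometry),
      full = calibration_params(g$full$P0, g$full$Ps, g$full$m),
      methods = lapply(g$methods, function(m) calibration_params(m$P0, m$Ps, m$m))
    )
  })
  list(universal = x$universal, geometries = geoms)
}
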