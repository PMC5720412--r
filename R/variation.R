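#' Ensemble of fitted calibration parameters
#'
#' Collects per-film parameter triples with day and batch labels, the raw
#' material for intra-day (same processing day, different films/batches) and
#' inter-day (months to years apart) variation analysis.
#'
#' @param params List of [calibration_params()], or a data frame with
#'   columns `p0`, `ps`, `m` (and optionally `day_id`, `batch_id`).
#' @param day_id,batch_id Label vectors recycled to the ensemble length;
#'   ignored when `params` is a data frame that already carries them.
#' @return An object of class `parameter_ensemble` wrapping a data frame.
#' @export
parameter_ensemble <- function(params, day_id = NA_character_,
                               batch_id = NA_character_) {
  if (is.data.frame(params)) {
    if (!all(c("p0", "ps", "m") %in% names(params))) {
      abort_parse("ensemble data frame needs columns p0, ps, m")
    }
    df <- params
    if (!"day_id" %in% names(df)) df$day_id <- rep_len(day_id, nrow(df))
    if (!"batch_id" %in% names(df)) df$batch_id <- rep_len(batch_id, nrow(df))
  } else if (is.list(params)) {
    lapply(params, assert_params)
    df <- data.frame(
      p0 = vapply(params, function(p) p$p0, numeric(1)),
      ps = vapply(params, function(p) p$ps, numeric(1)),
      m = vapply(params, function(p) p$m, numeric(1)),
      day_id = rep_len(as.character(day_id), length(params)),
      batch_id = rep_len(as.character(batch_id), length(params)))
  } else {
    abort_parse("params must be a list of calibration_params or a data frame")
  }
  if (any(df$ps <= 0) || any(df$m <= 0) || any(df$p0 < 0)) {
    abort_domain("ensemble entries must satisfy p0 >= 0, ps > 0, m > 0")
  }
  structure(list(entries = df[c("day_id", "batch_id", "p0", "ps", "m")]),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf("<parameter_ensemble> %d entries\n", nrow(x$entries)))
  print(utils::head(x$entries, 8), row.names = FALSE)
  invisible(x)
}

ensemble_params_list <- function(ens) {
  lapply(seq_len(nrow(ens$entries)), function(i) {
    e <- ens$entries[i, ]
    calibration_params(e$p0, e$ps, e$m)
  })
}

#' Per-parameter ensemble statistics
#'
#' Arithmetic mean, sample standard deviation (n-1 denominator, appropriate
#' for the small ensembles of 7-12 films typical in practice), and relative
#' SD in percent, for each of the three curve parameters.
#'
#' @param ens A [parameter_ensemble()] with at least 2 entries.
#' @return Data frame: `parameter`, `mean`, `sd`, `rel_sd_pct`.
#' @examples
#' ens <- parameter_ensemble(data.frame(p0 = c(244, 246), ps = c(3200, 3340),
#'                                      m = c(30, 33)))
#' ensemble_statistics(ens)
#' @export
ensemble_statistics <- function(ens) {
  if (!inherits(ens, "parameter_ensemble")) {
    abort_parse("ens must be a 'parameter_ensemble'")
  }
  if (nrow(ens$entries) < 2L) {
    abort_config("ensemble statistics need at least 2 entries")
  }
  stats_one <- function(v) {
    c(mean = mean(v), sd = stats::sd(v), rel_sd_pct = 100 * stats::sd(v) / mean(v))
  }
  res <- t(vapply(ens$entries[c("p0", "ps", "m")], stats_one, numeric(3)))
  data.frame(parameter = rownames(res), mean = res[, "mean"], sd = res[, "sd"],
             rel_sd_pct = res[, "rel_sd_pct"], row.names = NULL)
}

#' Maximum pairwise dose spread of a curve ensemble
#'
#' The worst-case local dose disagreement inside an ensemble: for every
#' ordered pair of curves (each member serving alternately as truth, since
#' no member is privileged) the [local_dose_error()] is evaluated over the
#' dose grid and the maximum absolute value is returned.
#'
#' @param ens A [parameter_ensemble()] with at least 2 entries.
#' @param dose_grid Doses, cGy; default 1-cGy steps over 10-128 cGy.
#' @return A list: `max_spread` (fractional), `worst_pair` (row indices),
#'   `flagged_pairs` (pairs with non-invertible grid points, if any).
#' @export
ensemble_dose_spread <- function(ens, dose_grid = seq(10, 128, by = 1)) {
  if (!inherits(ens, "parameter_ensemble")) {
    abort_parse("ens must be a 'parameter_ensemble'")
  }
  curves <- ensemble_params_list(ens)
  n <- length(curves)
  if (n < 2L) abort_config("dose spread needs at least 2 curves")
  max_spread <- 0
  worst <- c(NA_integer_, NA_integer_)
  flagged <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      for (pair in list(c(i, j), c(j, i))) {
        lde <- withCallingHandlers(
          local_dose_error(curves[[pair[1]]], curves[[pair[2]]], dose_grid),
          warning = function(w) {
            flagged[[length(flagged) + 1L]] <<- pair
            invokeRestart("muffleWarning")
          })
        if (!is.na(lde$max_abs_error) && lde$max_abs_error > max_spread) {
          max_spread <- lde$max_abs_error
          worst <- pair
        }
      }
    }
  }
  list(max_spread = max_spread, worst_pair = worst, flagged_pairs = flagged)
}
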