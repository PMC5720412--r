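#' @importFrom minpack.lm nls.lm nls.lm.control
#' @importFrom stats optimize uniroot coef qnorm sd rnorm quantile
NULL

# ---- internal helpers -------------------------------------------------------

# Closed-form slope from one point when p0 and ps are known:
# m = -(ps / D) * log(1 - (P - p0)/ps).
slope_one_point <- function(d, p, p0, ps) {
  net <- p - p0
  if (net <= 0) {
    abort_infeasible(sprintf(
      "exposed pixel value (%.6g) does not exceed the background (%.6g); slope undefined",
      p, p0))
  }
  if (net >= ps) {
    abort_infeasible(sprintf(
      "exposed pixel value (%.6g) at or beyond saturation p0 + ps = %.6g", p, p0 + ps))
  }
  -(ps / d) * log(1 - net / ps)
}

# 1-D least squares over m with p0, ps fixed. Deterministic: golden-section
# via optimize() on the bracket m*D/ps in (1e-6, 50).
fit_slope_ls <- function(dose, pixel, p0, ps, tol = 1e-10) {
  sse <- function(m) {
    sum((p0 + ps * (1 - exp(-m * dose / ps)) - pixel)^2)
  }
  lo <- 1e-6 * ps / max(dose)
  hi <- 50 * ps / min(dose)
  opt <- stats::optimize(sse, c(lo, hi), tol = tol * ps / max(dose))
  if (opt$minimum <= lo * (1 + 1e-6) || opt$minimum >= hi * (1 - 1e-6)) {
    abort_infeasible("slope fit hit the search bracket; data inconsistent with the response model")
  }
  opt$minimum
}

fit_result <- function(params, method, data, flags = character()) {
  resid <- data$points$pixel - pixel_from_dose(params, data$points$dose)
  structure(
    list(params = params, method = method,
         rms = sqrt(mean(resid^2)), residuals = resid,
         n = nrow(data$points), flags = flags),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> method %s, n = %d, residual RMS = %.4g counts\n",
              x$method, x$n, x$rms))
  print(x$params)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) coef(object$params)

# ---- full fit ---------------------------------------------------------------

#' Full nonlinear fit of the response curve
#'
#' Unweighted least squares of the saturation-exponential response model on
#' (dose, pixel) points by Levenberg-Marquardt. The background `p0` is fixed
#' to the dataset's unexposed-film value when one is present (the usual
#' workflow); with `fix_p0 = FALSE` and at least four points, `p0` is fitted
#' as a free parameter.
#'
#' Starting values: the slope from the secant through the lowest-dose point
#' and a saturation value of 1.2 times the largest net pixel, which keeps the
#' model feasible at the first iteration. Parameter positivity is enforced by
#' box constraints; a fit that needs to violate them fails rather than being
#' clipped.
#'
#' When the data do not probe saturation (all points in the near-linear
#' low-dose regime) the saturation parameter is unidentifiable: the fit is
#' flagged `"ps_unidentifiable"` with a warning when the model Jacobian is
#' numerically rank-deficient.
#'
#' @param data A [calibration_dataset()]; at least 3 points with a background
#'   (or `fix_p0 = FALSE` and at least 4 points).
#' @param fix_p0 Fix the background to `data$background` (default when a
#'   background is present).
#' @param tolerance Relative convergence tolerance on the parameters.
#' @param max_iter Iteration cap for the optimizer.
#' @return A `calibration_fit`: fitted [calibration_params()], residual RMS,
#'   residuals, and flags.
#' @examples
#' truth <- calibration_params(247, 3585, 30.80)
#' d <- c(16, 24, 32, 48, 64, 80, 96, 128)
#' fit_full(calibration_dataset(d, pixel_from_dose(truth, d), background = 247))
#' @export
fit_full <- function(data, fix_p0 = !is.null(data$background),
                     tolerance = 1e-8, max_iter = 200) {
  assert_dataset(data)
  dose <- data$points$dose
  pixel <- data$points$pixel
  if (fix_p0) {
    if (is.null(data$background)) {
      abort_config("fix_p0 = TRUE requires a background pixel value in the dataset")
    }
    if (n_points(data) < 3L) abort_config("full fit with fixed p0 needs >= 3 points")
  } else if (n_points(data) < 4L) {
    abort_config("full fit with free p0 needs >= 4 points")
  }

  p0_start <- if (!is.null(data$background)) data$background else 0.8 * min(pixel)
  net_max <- max(pixel) - p0_start
  if (net_max <= 0) {
    abort_infeasible("all pixel values at or below background; nothing to fit")
  }
  ps_start <- 1.2 * net_max
  m_start <- (pixel[1] - p0_start) / dose[1]
  if (m_start <= 0) abort_infeasible("lowest-dose point does not exceed background")

  if (fix_p0) {
    par0 <- c(ps = ps_start, m = m_start)
    resid_fn <- function(par) {
      p0_start + par[["ps"]] * (1 - exp(-par[["m"]] * dose / par[["ps"]])) - pixel
    }
    lower <- c(1e-8, 1e-8)
  } else {
    par0 <- c(p0 = p0_start, ps = ps_start, m = m_start)
    resid_fn <- function(par) {
      par[["p0"]] + par[["ps"]] * (1 - exp(-par[["m"]] * dose / par[["ps"]])) - pixel
    }
    lower <- c(0, 1e-8, 1e-8)
  }

  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn, lower = lower,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ptol = tolerance, ftol = tolerance)
  )
  if (!(fit$info %in% 1:4)) {
    abort_infeasible(sprintf("nonlinear fit failed to converge (%s)", fit$message))
  }
  est <- fit$par
  flags <- character()
  # Identifiability: if the data never reach ~5% of saturation the curvature
  # term (quadratic in m*D/ps) is below typical readout noise and ps is only
  # weakly constrained.
  frac_max <- 1 - exp(-est[["m"]] * max(dose) / est[["ps"]])
  if (frac_max < 0.05) {
    flags <- c(flags, "ps_unidentifiable")
    warning("saturation parameter is weakly identified: data do not probe curve bending",
            call. = FALSE)
  }
  p0_hat <- if (fix_p0) p0_start else est[["p0"]]
  params <- calibration_params(p0_hat, est[["ps"]], est[["m"]])
  fit_result(params, "full", data, flags)
}

# ---- reduced-point methods --------------------------------------------------

#' Method I: slope from universal background and saturation
#'
#' Fits only the sensitivity slope `m`, taking both the background and the
#' saturation pixel value from batch-level "universal" constants. With one
#' point the slope has the closed form
#' \eqn{m = -(P_s/D)\ln(1 - (P - P_0)/P_s)}; with two points it is the 1-D
#' least-squares slope.
#'
#' @param data A [calibration_dataset()] with 1 or 2 points.
#' @param universal_p0 Universal background pixel value.
#' @param universal_ps Universal saturation (net) pixel value.
#' @return A `calibration_fit` with method `"I"`.
#' @examples
#' truth <- calibration_params(245, 3542, 31.28)
#' d <- calibration_dataset(80, pixel_from_dose(truth, 80))
#' fit_method_I(d, universal_p0 = 245, universal_ps = 3542)
#' @export
fit_method_I <- function(data, universal_p0, universal_ps) {
  assert_dataset(data)
  if (!n_points(data) %in% 1:2) abort_config("Method I uses 1 or 2 dose points")
  if (missing(universal_p0) || missing(universal_ps)) {
    abort_config("Method I requires universal_p0 and universal_ps")
  }
  if (universal_ps <= 0 || universal_p0 < 0) {
    abort_config("universal parameters must satisfy p0 >= 0, ps > 0")
  }
  dose <- data$points$dose
  pixel <- data$points$pixel
  m <- if (length(dose) == 1L) {
    slope_one_point(dose, pixel, universal_p0, universal_ps)
  } else {
    if (any(pixel <= universal_p0) || any(pixel >= universal_p0 + universal_ps)) {
      abort_infeasible("a fitting point lies outside (universal p0, universal p0 + ps)")
    }
    fit_slope_ls(dose, pixel, universal_p0, universal_ps)
  }
  fit_result(calibration_params(universal_p0, universal_ps, m), "I", data)
}

#' Method II: slope from universal saturation and a measured background
#'
#' Like [fit_method_I()] but the background comes from an unexposed film of
#' the same batch (carried in the dataset), so only the saturation value is
#' universal.
#'
#' @param data A [calibration_dataset()] with a background and 1 or 2 points.
#' @param universal_ps Universal saturation (net) pixel value.
#' @return A `calibration_fit` with method `"II"`.
#' @export
fit_method_II <- function(data, universal_ps) {
  assert_dataset(data)
  if (is.null(data$background)) abort_config("Method II requires a background film value")
  if (!n_points(data) %in% 1:2) abort_config("Method II uses 1 or 2 dose points")
  if (missing(universal_ps) || universal_ps <= 0) {
    abort_config("Method II requires a positive universal_ps")
  }
  p0 <- data$background
  dose <- data$points$dose
  pixel <- data$points$pixel
  m <- if (length(dose) == 1L) {
    slope_one_point(dose, pixel, p0, universal_ps)
  } else {
    if (any(pixel <= p0) || any(pixel >= p0 + universal_ps)) {
      abort_infeasible("a fitting point lies outside (background, background + universal ps)")
    }
    fit_slope_ls(dose, pixel, p0, universal_ps)
  }
  fit_result(calibration_params(p0, universal_ps, m), "II", data)
}

#' Method III: saturation and slope from a background film and 2-3 points
#'
#' The background is measured; both `ps` and `m` come from the data. Two
#' points determine (`ps`, `m`) exactly: writing `u = m/ps`, the net-pixel
#' ratio \eqn{n_1/n_2 = (1 - e^{-u D_1})/(1 - e^{-u D_2})} is strictly
#' increasing in `u` from \eqn{D_1/D_2} (no bending) to 1 (full saturation),
#' so `u` is found by deterministic root bracketing and back-substituted.
#' Three points are fitted by least squares with the background fixed.
#'
#' A two-point dataset whose net pixel values are proportional to dose (or
#' sub-linear) carries no curvature information: the system has no positive
#' solution and the fit fails as unidentifiable/infeasible rather than
#' returning an extreme saturation value.
#'
#' @param data A [calibration_dataset()] with a background and 2 or 3 points.
#' @return A `calibration_fit` with method `"III"`.
#' @examples
#' truth <- calibration_params(254, 3209, 40.18)
#' d <- c(40, 120)
#' fit_method_III(calibration_dataset(d, pixel_from_dose(truth, d), background = 254))
#' @export
fit_method_III <- function(data) {
  assert_dataset(data)
  if (is.null(data$background)) abort_config("Method III requires a background film value")
  if (!n_points(data) %in% 2:3) abort_config("Method III uses 2 or 3 dose points")
  p0 <- data$background
  dose <- data$points$dose
  pixel <- data$points$pixel
  net <- pixel - p0
  if (any(net <= 0)) abort_infeasible("exposed pixel values must exceed the background")

  if (length(dose) == 2L) {
    r <- net[1] / net[2]
    r_linear <- dose[1] / dose[2]
    if (r <= r_linear * (1 + 1e-12)) {
      if (abs(r - r_linear) <= 1e-9 * r_linear) {
        abort_unidentifiable(
          "net pixel values are proportional to dose: saturation is unidentifiable from two points")
      }
      abort_infeasible(
        "net pixel values grow super-linearly with dose: no positive (ps, m) solution")
    }
    g <- function(u) (1 - exp(-u * dose[1])) / (1 - exp(-u * dose[2])) - r
    u <- stats::uniroot(g, lower = 1e-9 / dose[2], upper = 50 / dose[1],
                        tol = 1e-14)$root
    ps <- net[2] / (1 - exp(-u * dose[2]))
    m <- u * ps
    return(fit_result(calibration_params(p0, ps, m), "III", data))
  }

  fit <- fit_full(data, fix_p0 = TRUE)
  fit$method <- "III"
  fit
}

# ---- method dispatcher ------------------------------------------------------

#' Fit a calibration curve by a named strategy
#'
#' Thin dispatcher over [fit_full()], [fit_method_I()], [fit_method_II()] and
#' [fit_method_III()]; this is the entry point the command-line interface
#' uses.
#'
#' @param data A [calibration_dataset()].
#' @param method One of `"full"`, `"I"`, `"II"`, `"III"`.
#' @param universal_p0,universal_ps Universal parameters where the method
#'   requires them.
#' @param ... Passed through to the strategy function.
#' @return A `calibration_fit`.
#' @export
fit_calibration <- function(data, method = c("full", "I", "II", "III"),
                            universal_p0 = NULL, universal_ps = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    full = fit_full(data, ...),
    I = {
      if (is.null(universal_p0) || is.null(universal_ps)) {
        abort_usage("method I requires universal_p0 and universal_ps")
      }
      fit_method_I(data, universal_p0, universal_ps)
    },
    II = {
      if (is.null(universal_ps)) abort_usage("method II requires universal_ps")
      fit_method_II(data, universal_ps)
    },
    III = fit_method_III(data)
  )
}

# ---- two-step batch fit -----------------------------------------------------

#' Two-step batch fit with an optimal shared saturation value
#'
#' Films from one emulsion batch share a saturation pixel value (it reflects
#' the grain concentration), so a batch-level estimate is steadier than any
#' single film's. Step one fits every dataset freely; the optimal saturation
#' is the arithmetic mean of the fitted `ps` over all non-reference films
#' (multi-field reference films are excluded: inter-field scatter cross-talk
#' biases their fitted saturation low). Step two refits each film's slope
#' with `ps` fixed at the optimum.
#'
#' @param datasets List of [calibration_dataset()] objects from one batch,
#'   each fittable by [fit_full()]; at least two must not be flagged as
#'   reference films.
#' @return A list with `optimal_ps`, `step1` (free fits) and `fits` (refits
#'   at the shared saturation).
#' @export
fit_batch_two_step <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2L) {
    abort_config("two-step batch fitting needs a list of >= 2 datasets")
  }
  lapply(datasets, assert_dataset)
  step1 <- lapply(datasets, fit_full)
  is_ref <- vapply(datasets, function(d) d$reference, logical(1))
  if (sum(!is_ref) < 2L) {
    abort_config("at least two non-reference datasets are needed to average ps")
  }
  optimal_ps <- mean(vapply(step1[!is_ref], function(f) f$params$ps, numeric(1)))

  fits <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    p0 <- if (!is.null(d$background)) d$background else step1[[i]]$params$p0
    m <- fit_slope_ls(d$points$dose, d$points$pixel, p0, optimal_ps)
    f <- fit_result(calibration_params(p0, optimal_ps, m), "batch", d)
    f
  })
  list(optimal_ps = optimal_ps, step1 = step1, fits = fits)
}
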