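# Dose-uncertainty budget for the inverted calibration curve
# D = -(ps/m) log(1 - (P - p0)/ps), split into a systematic component from
# the fitted parameters (ps, m) and a random component from the measurement
# (P) and background (p0).

#' Relative 1-sigma uncertainty budget
#'
#' @param ps,m,p,p0 Relative (fractional) 1-sigma uncertainties of the
#'   saturation value, sensitivity slope, measured pixel value, and
#'   background. E.g. `0.01` is 1%.
#' @return An object of class `uncertainty_budget`.
#' @examples
#' uncertainty_budget(ps = 0.005, m = 0.01, p = 0.01, p0 = 0.005)
#' @export
uncertainty_budget <- function(ps = 0, m = 0, p = 0, p0 = 0) {
  v <- c(ps = ps, m = m, p = p, p0 = p0)
  if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
    abort_domain("budget components must be finite and >= 0")
  }
  structure(as.list(v), class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat(sprintf("<uncertainty_budget> 1-sigma: ps %.3g%%, m %.3g%%, P %.3g%%, p0 %.3g%%\n",
              100 * x$ps, 100 * x$m, 100 * x$p, 100 * x$p0))
  invisible(x)
}

#' Rounded midrange propagation weights
#'
#' The conventional rounded weights (0.25, 1, 3, 0.05) applied to the squared
#' relative uncertainties of (saturation, slope, pixel, background) when the
#' dose error is evaluated at film-response midrange. These are rounded
#' versions of the exact partial-derivative weights returned by
#' [propagation_coefficients()] at `response_fraction = 0.5` for typical
#' parameter magnitudes.
#'
#' @return Named numeric vector `c(ps, m, p, p0)`.
#' @export
rounded_coefficients <- function() c(ps = 0.25, m = 1, p = 3, p0 = 0.05)

#' Exact propagation coefficients from the model partial derivatives
#'
#' For a pixel value at net response fraction `f = (P - p0)/ps`, the dose is
#' \eqn{D = -(ps/m)\ln(1-f)} and the squared relative-error weights are the
#' squared logarithmic sensitivities \eqn{(\partial D/\partial x \cdot x /
#' D)^2} for x in (ps, m, P, p0), with the pixel term expressed against the
#' *total* pixel value P and the background term against p0:
#' \itemize{
#'   \item \eqn{c_{ps} = (1 + f/((1-f)\ln(1-f)))^2}
#'   \item \eqn{c_m = 1} exactly (since \eqn{\partial D/\partial m = -D/m})
#'   \item \eqn{c_P = (P / (m (1-f) D))^2}
#'   \item \eqn{c_{p0} = (p_0 / (m (1-f) D))^2}
#' }
#'
#' @param params A [calibration_params()] object.
#' @param response_fraction Net response fraction `f` in (0, 1); 0.5 is the
#'   curve's midrange, where the budget is conventionally quoted.
#' @return Named numeric vector `c(ps, m, p, p0)` with attributes `dose` and
#'   `pixel` giving the evaluation point.
#' @examples
#' propagation_coefficients(calibration_params(245, 3271, 31.7))
#' @export
propagation_coefficients <- function(params, response_fraction = 0.5) {
  assert_params(params)
  f <- response_fraction
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
    abort_domain("response_fraction must lie strictly between 0 and 1")
  }
  d <- -(params$ps / params$m) * log(1 - f)
  p_tot <- params$p0 + f * params$ps
  c_ps <- (1 + f / ((1 - f) * log(1 - f)))^2
  c_p <- (p_tot / (params$m * (1 - f) * d))^2
  c_p0 <- (params$p0 / (params$m * (1 - f) * d))^2
  structure(c(ps = c_ps, m = 1, p = c_p, p0 = c_p0), dose = d, pixel = p_tot)
}

#' Analytic dose-uncertainty propagation
#'
#' First-order propagation of the budget through the inverted calibration
#' curve: \deqn{(\sigma_D/D)^2 = \left[c_{ps}(\sigma_{ps}/ps)^2 +
#' c_m(\sigma_m/m)^2\right] + \left[c_P(\sigma_P/P)^2 +
#' c_{p0}(\sigma_{p0}/p_0)^2\right].} The first bracket is the systematic
#' component (repeated measurements share the fitted ps and m); the second
#' is the random component (each measurement has its own pixel and
#' background realisation).
#'
#' @param budget An [uncertainty_budget()].
#' @param coefficients Propagation weights `c(ps, m, p, p0)`; defaults to
#'   the rounded midrange quadruple [rounded_coefficients()]. Pass
#'   [propagation_coefficients()] output for exact weights at a specific
#'   curve and response fraction.
#' @return A list of class `error_budget`: `rel_sigma_d`, `systematic`,
#'   `random` (all fractional 1-sigma), and the `coefficients` used.
#' @examples
#' b <- uncertainty_budget(ps = 0.005, m = 0.01, p = 0.01, p0 = 0.005)
#' propagate_analytic(b)  # ~2% relative dose uncertainty
#' @export
propagate_analytic <- function(budget, coefficients = rounded_coefficients()) {
  if (!inherits(budget, "uncertainty_budget")) {
    abort_parse("budget must be an 'uncertainty_budget'")
  }
  co <- coefficients[c("ps", "m", "p", "p0")]
  if (any(is.na(co)) || any(co < 0)) {
    abort_domain("coefficients must be a named non-negative vector c(ps, m, p, p0)")
  }
  sys2 <- co[["ps"]] * budget$ps^2 + co[["m"]] * budget$m^2
  ran2 <- co[["p"]] * budget$p^2 + co[["p0"]] * budget$p0^2
  structure(
    list(rel_sigma_d = sqrt(sys2 + ran2),
         systematic = sqrt(sys2), random = sqrt(ran2),
         coefficients = co),
    class = "error_budget"
  )
}

#' @export
print.error_budget <- function(x, ...) {
  cat(sprintf(
    "<error_budget> sigma_D/D = %.3g%% (systematic %.3g%%, random %.3g%%)\n",
    100 * x$rel_sigma_d, 100 * x$systematic, 100 * x$random))
  invisible(x)
}

#' Monte-Carlo dose-uncertainty propagation
#'
#' Cross-checks [propagate_analytic()] by direct simulation: the saturation,
#' slope and background are perturbed by independent Gaussian relative
#' errors, the observed pixel value (taken from the unperturbed curve at
#' `dose`) is perturbed by the pixel budget, and each draw is inverted to
#' dose. Returns the sample SD of the relative dose error with a bootstrap
#' confidence interval.
#'
#' Draws whose perturbed pixel value falls at or beyond the perturbed
#' saturation cannot be inverted; if more than 1% of draws are lost this way
#' the simulation aborts (the budget is too large for the linear regime the
#' analytic budget assumes).
#'
#' @param params A [calibration_params()] object (true curve).
#' @param budget An [uncertainty_budget()].
#' @param dose Evaluation dose, cGy. Defaults to the midrange-response dose
#'   of the curve.
#' @param n_draws Number of Monte-Carlo draws (>= 1000).
#' @param seed RNG seed; the result is deterministic for a fixed seed.
#' @param n_boot Bootstrap resamples for the CI on the SD.
#' @param conf CI level.
#' @return List: `rel_sigma_d`, `ci` (bootstrap percentile interval), `se`
#'   (bootstrap SE), `n_draws`, `n_invalid`.
#' @export
propagate_monte_carlo <- function(params, budget, dose = NULL,
                                  n_draws = 10000, seed = NULL,
                                  n_boot = 200, conf = 0.95) {
  assert_params(params)
  if (!inherits(budget, "uncertainty_budget")) {
    abort_parse("budget must be an 'uncertainty_budget'")
  }
  if (n_draws < 1000) abort_config("n_draws must be >= 1000")
  if (is.null(dose)) {
    dose <- -(params$ps / params$m) * log(0.5)  # midrange response
  }
  if (dose <= 0) abort_domain("dose must be positive")
  p_true <- pixel_from_dose(params, dose)

  with_seed(seed, {
    ps_d <- params$ps * (1 + stats::rnorm(n_draws, 0, budget$ps))
    m_d <- params$m * (1 + stats::rnorm(n_draws, 0, budget$m))
    p0_d <- params$p0 * (1 + stats::rnorm(n_draws, 0, budget$p0))
    p_obs <- p_true * (1 + stats::rnorm(n_draws, 0, budget$p))
    frac <- (p_obs - p0_d) / ps_d
    ok <- ps_d > 0 & m_d > 0 & frac < 1 - 1e-12
    n_invalid <- sum(!ok)
    if (n_invalid > 0.01 * n_draws) {
      abort_infeasible(sprintf(
        "%.1f%% of Monte-Carlo draws were non-invertible; budget too large for this dose",
        100 * n_invalid / n_draws))
    }
    d_hat <- -(ps_d[ok] / m_d[ok]) * log(1 - frac[ok])
    rel_err <- d_hat / dose - 1
    sd_hat <- stats::sd(rel_err)
    n_ok <- length(rel_err)
    boot <- vapply(seq_len(n_boot), function(i) {
      stats::sd(rel_err[sample.int(n_ok, n_ok, replace = TRUE)])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    list(rel_sigma_d = sd_hat,
         ci = stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE),
         se = stats::sd(boot),
         n_draws = n_draws, n_invalid = n_invalid)
  })
}

#' Parameter-influence dose-error curves
#'
#' Shows how a daily excursion of each calibration parameter, taken alone at
#' a given confidence level, distorts inverted doses: each parameter is
#' perturbed by plus and minus `z` times its budgeted relative sigma (z from
#' the confidence level) and the perturbed curve's [local_dose_error()]
#' against the unperturbed curve is evaluated over the dose grid.
#'
#' Characteristic shapes: a background excursion dominates only below ~10
#' cGy; a saturation excursion grows with dose; a slope excursion gives a
#' nearly constant relative error at all doses (to first order
#' \eqn{-\Delta m/m}), which is why processing variation matters most in the
#' useful dose range.
#'
#' @param params A [calibration_params()] object (unperturbed curve).
#' @param budget An [uncertainty_budget()]; the `p` (pixel) component is a
#'   measurement property, not a curve parameter, and is ignored here.
#' @param dose_grid Doses, cGy.
#' @param confidence Two-sided confidence level mapping to the z-multiple.
#' @return Data frame: `parameter`, `direction` (+1/-1), `z`, `dose`,
#'   `rel_error`.
#' @export
parameter_influence_curves <- function(params, budget,
                                       dose_grid = seq(1, 128, by = 1),
                                       confidence = 0.95) {
  assert_params(params)
  if (!inherits(budget, "uncertainty_budget")) {
    abort_parse("budget must be an 'uncertainty_budget'")
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  out <- list()
  for (par in c("p0", "ps", "m")) {
    for (dir in c(1, -1)) {
      delta <- dir * z * budget[[par]]
      pert <- list(p0 = params$p0, ps = params$ps, m = params$m)
      pert[[par]] <- pert[[par]] * (1 + delta)
      test <- calibration_params(pert$p0, pert$ps, pert$m)
      lde <- suppressWarnings(local_dose_error(test, params, dose_grid))
      out[[length(out) + 1L]] <- data.frame(
        parameter = par, direction = dir, z = z,
        dose = lde$table$dose, rel_error = lde$table$rel_error)
    }
  }
  do.call(rbind, out)
}
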