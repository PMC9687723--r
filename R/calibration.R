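#' Fit a concentration calibration curve
#'
#' Ordinary least-squares line relating a scalar spectral response (DMi at
#' a chosen frequency, or the effective capacitance in F) to suspension
#' concentration:
#' \deqn{response = slope \cdot c + intercept.}
#' The slope is the sensitivity of the method (response units per
#' particle/uL) and R^2 measures goodness of fit. An optional
#' log10-concentration regressor is available for responses that saturate
#' at high loading, but the plain linear form is the default.
#'
#' @param concentrations Concentrations in particles (or cells) per uL;
#'   strictly positive, distinct, length >= 3.
#' @param responses Scalar response per concentration; must not be
#'   constant.
#' @param log_concentration Regress on log10(concentration) instead of
#'   concentration (default `FALSE`).
#' @return An object of class `"calibration_curve"`: fields
#'   `concentrations`, `responses`, `slope`, `intercept`, `r_squared`,
#'   `n`, `log_concentration`.
#' @seealso [predict_concentration()]
#' @examples
#' cc <- fit_calibration(c(25, 50, 100, 200, 400),
#'                       0.5e-6 + 5e-10 * c(25, 50, 100, 200, 400))
#' cc$r_squared
#' @export
fit_calibration <- function(concentrations, responses,
                            log_concentration = FALSE) {
  if (!is.numeric(concentrations) || !is.numeric(responses)) {
    stop("concentrations and responses must be numeric", call. = FALSE)
  }
  if (length(concentrations) != length(responses)) {
    stop("concentrations and responses must have equal length", call. = FALSE)
  }
  if (length(concentrations) < 3) {
    stop("at least 3 calibration points are required", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("concentrations must be distinct", call. = FALSE)
  }
  if (stats::sd(responses) == 0) {
    stop("responses have zero variance; no calibration line exists",
         call. = FALSE)
  }
  x <- if (log_concentration) log10(concentrations) else concentrations
  fit <- stats::lm(responses ~ x)
  # R^2 computed directly; summary.lm() warns on exact fits
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((responses - mean(responses))^2)
  structure(list(
    concentrations = concentrations,
    responses = responses,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n = length(concentrations),
    log_concentration = log_concentration
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve (%d points, %s regressor):\n", x$n,
              if (x$log_concentration) "log10(conc)" else "conc"))
  cat(sprintf("  sensitivity (slope): %.4g per (count/uL)\n", x$slope))
  cat(sprintf("  intercept: %.4g   R^2: %.4f\n", x$intercept, x$r_squared))
  invisible(x)
}

#' Estimate concentration from a measured response
#'
#' Inverts the calibration line: `c = (response - intercept) / slope`. A
#' prediction outside the calibrated concentration range is still returned
#' but flagged and warned about, since the linearity of the response is
#' only established inside the range.
#'
#' @param curve A [fit_calibration()] result.
#' @param response Measured scalar response.
#' @return Estimated concentration (per uL), with attribute
#'   `"extrapolated"` set when outside \[min, max\] of the calibration
#'   concentrations.
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(response) || length(response) != 1 || !is.finite(response)) {
    stop("response must be a single finite number", call. = FALSE)
  }
  if (curve$slope == 0) {
    stop("calibration slope is zero; concentration is not identifiable",
         call. = FALSE)
  }
  xhat <- (response - curve$intercept) / curve$slope
  conc <- if (curve$log_concentration) 10^xhat else xhat
  rng <- range(curve$concentrations)
  eps <- 1e-8 * diff(rng)  # boundary points count as in-range
  outside <- conc < rng[1] - eps | conc > rng[2] + eps
  if (outside) {
    warning(sprintf("predicted concentration %.4g/uL is outside the calibrated range [%.4g, %.4g]",
                    conc, min(curve$concentrations), max(curve$concentrations)),
            call. = FALSE)
  }
  attr(conc, "extrapolated") <- outside
  conc
}
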