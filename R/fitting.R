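#' Configuration for circuit fitting
#'
#' Settings for the complex nonlinear least-squares fit of the equivalent
#' circuit (see [fit_circuit()]).
#'
#' @param weighting `"modulus"` (residuals divided by |Z_obs| per
#'   frequency; default, since |Z| spans about a decade over the band and
#'   unweighted residuals would let the low-frequency points dominate) or
#'   `"unit"`.
#' @param max_iterations Optimizer iteration cap per start.
#' @param tolerance Relative convergence threshold passed to the optimizer
#'   (ftol/ptol). Tight by default so noiseless fits reach machine
#'   precision.
#' @param n_starts Number of multistart launches (>= 1): the first from the
#'   heuristic [initial_guess()] (or a user `init`), the rest jittered
#'   around it.
#' @param seed Seed for the multistart jitter (kept local; the caller's RNG
#'   state is untouched).
#' @param bounds Named list with numeric vectors `lower` and `upper` over
#'   `ts, ps, ce, rd, td, pd` (natural units). Box bounds keep the CPE
#'   exponents in \[0, 1\] and all magnitudes positive during optimization.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(weighting = c("modulus", "unit"),
                       max_iterations = 300,
                       tolerance = 1e-15,
                       n_starts = 8,
                       seed = 1,
                       bounds = default_bounds()) {
  weighting <- match.arg(weighting)
  stopifnot(max_iterations >= 1, tolerance > 0, n_starts >= 1)
  nm <- c("ts", "ps", "ce", "rd", "td", "pd")
  if (!is.list(bounds) || !all(c("lower", "upper") %in% names(bounds)) ||
      !all(nm %in% names(bounds$lower)) || !all(nm %in% names(bounds$upper))) {
    stop("bounds must be a list with named 'lower' and 'upper' vectors over ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  if (any(bounds$lower[nm] >= bounds$upper[nm])) {
    stop("each lower bound must be below its upper bound", call. = FALSE)
  }
  if (bounds$lower[["ps"]] < 0 || bounds$upper[["ps"]] > 1 ||
      bounds$lower[["pd"]] < 0 || bounds$upper[["pd"]] > 1) {
    stop("exponent bounds must stay within [0, 1]", call. = FALSE)
  }
  if (any(bounds$lower[c("ts", "ce", "rd", "td")] <= 0)) {
    stop("lower bounds for ts, ce, rd, td must be strictly positive",
         call. = FALSE)
  }
  structure(list(weighting = weighting, max_iterations = max_iterations,
                 tolerance = tolerance, n_starts = n_starts, seed = seed,
                 bounds = bounds),
            class = "fit_config")
}

#' @rdname fit_config
#' @export
default_bounds <- function() {
  list(
    lower = c(ts = 1e-12, ps = 0, ce = 1e-12, rd = 1, td = 1e-12, pd = 0.05),
    upper = c(ts = 10,    ps = 1, ce = 10,    rd = 1e9, td = 10,  pd = 1)
  )
}

# Internal parameterization for optimization: log10 on the scale-type
# parameters (ts, ce, rd, td), linear on the exponents. Log scaling makes
# the box bounds symmetric in decades and conditions the Jacobian.
theta_pack <- function(p) {
  c(log10(p$ts), p$ps, log10(p$ce), log10(p$rd), log10(p$td), p$pd)
}
theta_unpack <- function(th) {
  list(ts = 10^th[1], ps = th[2], ce = 10^th[3],
       rd = 10^th[4], td = 10^th[5], pd = th[6])
}
bounds_pack <- function(b) {
  list(lower = c(log10(b$lower[["ts"]]), b$lower[["ps"]], log10(b$lower[["ce"]]),
                 log10(b$lower[["rd"]]), log10(b$lower[["td"]]), b$lower[["pd"]]),
       upper = c(log10(b$upper[["ts"]]), b$upper[["ps"]], log10(b$upper[["ce"]]),
                 log10(b$upper[["rd"]]), log10(b$upper[["td"]]), b$upper[["pd"]]))
}

#' Weighted complex residuals of the circuit model
#'
#' Residual vector minimized by [fit_circuit()]: real and imaginary parts
#' of `Z_model - Z_obs` at every frequency, stacked as
#' `c(Re(...), Im(...))` and divided pointwise by the weight `w(f)` --
#' 1 for `"unit"` weighting, `|Z_obs(f)|` for `"modulus"` weighting.
#' Length is twice the number of frequencies.
#'
#' @param params A [circuit_params()] object (or coercible named list).
#' @param observed An [eis_spectrum()].
#' @param weighting `"modulus"` or `"unit"`.
#' @return Numeric vector of length `2 * length(observed$frequency_hz)`.
#' @export
circuit_residuals <- function(params, observed,
                              weighting = c("modulus", "unit")) {
  weighting <- match.arg(weighting)
  params <- as_circuit_params(params)
  stopifnot(inherits(observed, "eis_spectrum"))
  zm <- circuit_impedance(params, observed$frequency_hz)$z
  d <- zm - observed$z
  w <- if (weighting == "modulus") Mod(observed$z) else rep(1, length(d))
  if (any(w <= 0)) stop("observed spectrum has zero magnitude points", call. = FALSE)
  c(Re(d) / w, Im(d) / w)
}

#' Heuristic starting parameters from a measured spectrum
#'
#' Data-driven initial guess for [fit_circuit()]:
#' * `ce` from the highest-frequency point, where the electrode capacitance
#'   shorts the parallel block: `ce ~ -1/(omega * Im(Z))`;
#' * `rd` from the real-axis extent of the Nyquist arc;
#' * `td`, `pd` at nominal dispersed-EDL values (1e-6 F s^(P-1), 0.75);
#' * `ts`, `ps` read from the lowest-frequency point *after subtracting*
#'   the parallel block estimated from the above -- the block dominates
#'   |Z| at low frequency, so the raw phase there reflects the block, not
#'   the series CPE.
#' All components are clipped into `bounds`, so the guess is always a valid
#' starting point.
#'
#' @param observed An [eis_spectrum()].
#' @param bounds Box bounds as in [fit_config()].
#' @return A [circuit_params()] object inside the bounds.
#' @export
initial_guess <- function(observed, bounds = default_bounds()) {
  stopifnot(inherits(observed, "eis_spectrum"))
  f <- observed$frequency_hz
  z <- observed$z
  n <- length(f)
  w_hi <- 2 * pi * f[n]

  ce <- if (Im(z[n]) < 0) -1 / (w_hi * Im(z[n])) else 1e-6
  ce <- clamp(ce, bounds$lower[["ce"]], bounds$upper[["ce"]])
  rd <- clamp(max(Re(z)) - min(Re(z)), bounds$lower[["rd"]], bounds$upper[["rd"]])
  td <- clamp(1e-6, bounds$lower[["td"]], bounds$upper[["td"]])
  pd <- clamp(0.75, bounds$lower[["pd"]], bounds$upper[["pd"]])

  # strip the estimated parallel block, read the series CPE off the remainder
  omega <- 2 * pi * f
  z_series <- z - 1 / (1i * omega * ce + 1 / rd + td * (1i * omega)^pd)
  ps <- -Arg(z_series[1]) / (pi / 2)
  if (!is.finite(ps) || ps <= 0 || ps > 1 || Re(z_series[1]) <= 0) ps <- 0.3
  m1 <- Mod(z_series[1])
  ts <- if (is.finite(m1) && m1 > 0) 1 / (m1 * omega[1]^ps) else 1e-3
  ps <- clamp(ps, bounds$lower[["ps"]], bounds$upper[["ps"]])
  ts <- clamp(ts, bounds$lower[["ts"]], bounds$upper[["ts"]])

  circuit_params(ts = ts, ps = ps, ce = ce, rd = rd, td = td, pd = pd)
}

#' Fit the equivalent circuit to a measured spectrum
#'
#' Estimates the six circuit parameters from a complex impedance spectrum
#' by bounded Levenberg--Marquardt least squares on the stacked
#' real/imaginary residuals (see [circuit_residuals()]), then derives the
#' effective capacitance from the estimates. Magnitude-type parameters are
#' optimized on a log10 scale. A seeded multistart (first start from the
#' heuristic guess or `init`, subsequent starts jittered around it:
#' +-1.5 decades on `ts`, +-0.5 on `td`, +-1 decade on `ce` and `rd`,
#' +-0.3 / +-0.15 on `ps` / `pd`, clipped to bounds) guards against the
#' local minima CPE models are known for. The lowest final cost wins; ties break toward the
#' earlier start.
#'
#' @param observed An [eis_spectrum()] with at least 4 frequencies (6
#'   parameters need >= 3 complex points; one extra is required for
#'   conditioning).
#' @param config A [fit_config()].
#' @param init Optional [circuit_params()] used as the first start instead
#'   of [initial_guess()].
#' @return An object of class `"circuit_fit"`: `params` (fitted
#'   [circuit_params()]), `cef` (effective capacitance, F), `cost` (final
#'   weighted residual sum of squares), `converged` (FALSE when the best
#'   start hit the iteration cap -- returned, not raised), `n_evaluations`
#'   (optimizer iterations of the winning start), `start_index`,
#'   `weighting`.
#' @examples
#' truth <- circuit_params(0.86e-3, 0.31, 0.57e-6, 3815, 9.9e-7, 0.73)
#' obs <- circuit_impedance(truth, log_freq_grid())
#' fit <- fit_circuit(obs)
#' fit$cef * 1e6  # uF
#' @export
fit_circuit <- function(observed, config = fit_config(), init = NULL) {
  stopifnot(inherits(observed, "eis_spectrum"), inherits(config, "fit_config"))
  if (length(observed$frequency_hz) < 4) {
    stop("at least 4 frequencies are required to fit 6 parameters",
         call. = FALSE)
  }
  b <- bounds_pack(config$bounds)
  g <- if (is.null(init)) initial_guess(observed, config$bounds)
       else as_circuit_params(init)
  th0 <- clamp(theta_pack(g), b$lower, b$upper)

  wt <- if (config$weighting == "modulus") Mod(observed$z)
        else rep(1, length(observed$z))
  if (any(wt <= 0)) stop("observed spectrum has zero-magnitude points", call. = FALSE)
  omega <- 2 * pi * observed$frequency_hz
  resid_fn <- function(th) {
    p <- theta_unpack(th)
    zm <- 1 / (p$ts * (1i * omega)^p$ps) +
      1 / (1i * omega * p$ce + 1 / p$rd + p$td * (1i * omega)^p$pd)
    d <- zm - observed$z
    c(Re(d) / wt, Im(d) / wt)
  }

  jitter_scale <- c(1.5, 0.3, 1.0, 1, 0.5, 0.15)
  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = config$tolerance,
                                     ptol = config$tolerance)
  best <- NULL
  best_idx <- NA_integer_
  failures <- character(0)
  with_seed(config$seed, {
    for (s in seq_len(config$n_starts)) {
      th_s <- if (s == 1) th0 else {
        clamp(th0 + stats::runif(6, -jitter_scale, jitter_scale),
              b$lower, b$upper)
      }
      res <- tryCatch(
        minpack.lm::nls.lm(par = th_s, lower = b$lower, upper = b$upper,
                           fn = resid_fn, control = ctrl),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("start %d: %s", s, conditionMessage(res)))
        next
      }
      if (is.null(best) || res$deviance < best$deviance) {
        best <- res
        best_idx <- s
      }
    }
  })
  if (is.null(best)) {
    stop("all ", config$n_starts, " starts failed:\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  }
  p_hat <- theta_unpack(best$par)
  params <- circuit_params(p_hat$ts, p_hat$ps, p_hat$ce,
                           p_hat$rd, p_hat$td, p_hat$pd)
  structure(list(
    params = params,
    cef = effective_capacitance(params),
    cost = best$deviance,
    converged = best$info %in% 1:4,
    n_evaluations = best$niter,
    start_index = best_idx,
    weighting = config$weighting
  ), class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("Equivalent-circuit fit",
      if (!x$converged) "(NOT converged: iteration cap reached)", "\n")
  print(x$params)
  cat(sprintf("  Cef = %.4g F (%.3g uF)   cost = %.4g (%s weighting)\n",
              x$cef, x$cef * 1e6, x$cost, x$weighting))
  cat(sprintf("  winning start %d, %d iterations\n",
              x$start_index, x$n_evaluations))
  invisible(x)
}

#' @export
coef.circuit_fit <- function(object, ...) {
  unlist(object$params)
}
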