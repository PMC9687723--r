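#' Constant phase element impedance
#'
#' Impedance of a constant phase element (CPE),
#' \deqn{Z_{CPE}(\omega) = \frac{1}{T (j\omega)^P}
#'     = \frac{1}{T\omega^P}\left(\cos\frac{\pi P}{2} - j \sin\frac{\pi P}{2}\right),}
#' with \eqn{\omega = 2\pi f}. The CPE models the non-ideal (dispersed)
#' capacitive behaviour of rough or heterogeneous charged interfaces:
#' `cpe_P = 1` is an ideal capacitor of capacitance `cpe_T`, `cpe_P = 0` an
#' ideal resistor of resistance `1/cpe_T`. The phase is `-cpe_P * 90`
#' degrees at every frequency.
#'
#' @param cpe_T CPE constant in F s^(P-1), strictly positive.
#' @param cpe_P CPE exponent, dimensionless, in \[0, 1\].
#' @param frequency_hz Frequency (Hz), strictly positive; vectorized.
#' @return Complex impedance in Ohm, same length as `frequency_hz`.
#' @examples
#' cpe_impedance(1, 0, 50)        # 1 Ohm ideal resistor
#' cpe_impedance(1e-6, 1, 50)     # ideal 1 uF capacitor
#' @export
cpe_impedance <- function(cpe_T, cpe_P, frequency_hz) {
  if (!is.numeric(cpe_T) || length(cpe_T) != 1 || !is.finite(cpe_T) || cpe_T <= 0) {
    stop("cpe_T must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(cpe_P) || length(cpe_P) != 1 || !is.finite(cpe_P) ||
      cpe_P < 0 || cpe_P > 1) {
    stop("cpe_P must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(frequency_hz) || any(!is.finite(frequency_hz)) ||
      any(frequency_hz <= 0)) {
    stop("frequency_hz must be strictly positive", call. = FALSE)
  }
  omega <- 2 * pi * frequency_hz
  1 / (cpe_T * (1i * omega)^cpe_P)
}

#' Equivalent-circuit parameter set for a suspension
#'
#' The six element values of the equivalent circuit used to model the
#' low-frequency impedance of a particle or non-adherent cell suspension:
#' a series CPE for the bulk suspension (`ts`, `ps`), in series with the
#' parallel combination of the electrode double-layer capacitance `ce` and
#' the dispersed-medium branch (`rd` shunted by a CPE `td`, `pd`
#' representing the multiple double layers around the suspended
#' particles/cells).
#'
#' @param ts Bulk-suspension CPE constant, F s^(P-1), > 0.
#' @param ps Bulk-suspension CPE exponent, in \[0, 1\].
#' @param ce Electrode double-layer capacitance, F, > 0.
#' @param rd Dispersed-medium double-layer resistance, Ohm, > 0.
#' @param td Dispersed-medium CPE constant, F s^(P-1), > 0.
#' @param pd Dispersed-medium CPE exponent, in \[0, 1\].
#' @return An object of class `"circuit_params"` (named list, SI units).
#' @seealso [circuit_impedance()], [effective_capacitance()]
#' @examples
#' circuit_params(ts = 0.1, ps = 0.3, ce = 1e-6, rd = 1e4, td = 1e-6, pd = 0.7)
#' @export
circuit_params <- function(ts, ps, ce, rd, td, pd) {
  vals <- c(ts = ts, ps = ps, ce = ce, rd = rd, td = td, pd = pd)
  if (!is.numeric(vals) || length(vals) != 6 || any(!is.finite(vals))) {
    stop("all six circuit parameters must be finite numbers", call. = FALSE)
  }
  if (ts <= 0 || ce <= 0 || rd <= 0 || td <= 0) {
    stop("ts, ce, rd and td must be strictly positive", call. = FALSE)
  }
  if (ps < 0 || ps > 1 || pd < 0 || pd > 1) {
    stop("ps and pd must lie in [0, 1]", call. = FALSE)
  }
  structure(list(ts = ts, ps = ps, ce = ce, rd = rd, td = td, pd = pd),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters:\n")
  cat(sprintf("  bulk CPE:       Ts = %.4g F s^(P-1), Ps = %.3f\n", x$ts, x$ps))
  cat(sprintf("  electrode:      Ce = %.4g F (%.3g uF)\n", x$ce, x$ce * 1e6))
  cat(sprintf("  dispersed EDL:  Rd = %.4g Ohm, Td = %.4g F s^(P-1), Pd = %.3f\n",
              x$rd, x$td, x$pd))
  invisible(x)
}

as_circuit_params <- function(p) {
  if (inherits(p, "circuit_params")) return(p)
  if (is.list(p) || is.numeric(p)) {
    p <- as.list(p)
    if (all(c("ts", "ps", "ce", "rd", "td", "pd") %in% names(p))) {
      return(circuit_params(p$ts, p$ps, p$ce, p$rd, p$td, p$pd))
    }
  }
  stop("expected a circuit_params object or a named list with ",
       "ts, ps, ce, rd, td, pd", call. = FALSE)
}

#' Full-circuit impedance spectrum
#'
#' Evaluates the suspension equivalent circuit over a frequency grid:
#' \deqn{Z(\omega) = Z_{CPE_s}(\omega) +
#'   \left[\frac{1}{j\omega C_e}\; \| \; R_d \; \| \; Z_{CPE_d}(\omega)\right],}
#' i.e. the bulk-suspension CPE in series with a three-way parallel block:
#' the electrode double-layer capacitance against the dispersed-medium
#' double layers, the latter modelled as a resistance shunted by a CPE.
#' The R-parallel-CPE element is the constant-phase generalization of a
#' Cole--Cole relaxation: it produces the depressed semicircle seen at the
#' high-frequency end of the Nyquist plot, and its effective capacitance
#' is exactly [dispersed_capacitance()], which sits in parallel with `ce`
#' so that the total is [effective_capacitance()]. Any passive network of
#' this form has phase in \[-90, 0\] degrees and |Z| -> 0 as
#' f -> infinity.
#'
#' The parallel block is evaluated as an admittance sum,
#' `1 / (j w Ce + 1/Rd + Td (j w)^Pd)`.
#'
#' @param params A [circuit_params()] object.
#' @param frequency_hz Frequency grid in Hz (strictly positive), e.g.
#'   [log_freq_grid()].
#' @return An [eis_spectrum()].
#' @examples
#' p <- circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7)
#' s <- circuit_impedance(p, log_freq_grid())
#' range(impedance_phase(s))
#' @export
circuit_impedance <- function(params, frequency_hz) {
  params <- as_circuit_params(params)
  validate_grid(frequency_hz)
  omega <- 2 * pi * frequency_hz
  z_s <- 1 / (params$ts * (1i * omega)^params$ps)
  y_block <- 1i * omega * params$ce + 1 / params$rd +
    params$td * (1i * omega)^params$pd
  z <- z_s + 1 / y_block
  eis_spectrum(frequency_hz, z)
}

#' Effective capacitance of the dispersed-medium branch
#'
#' Converts the dispersed-medium CPE (`td`, `pd`) and its series
#' double-layer resistance `rd` into a single equivalent capacitance via
#' the Cole--Cole analogy:
#' \deqn{C_d = \left(T_d \, R_d^{\,1 - P_d}\right)^{1/P_d}.}
#' Strictly increasing in both `td` and `rd`; at `pd = 1` it reduces to
#' `td` exactly. `pd = 0` is rejected (the exponent `1/pd` is singular
#' there, and the CPE degenerates to a resistor with no capacitance to
#' assign).
#'
#' @param rd Double-layer resistance, Ohm, > 0.
#' @param td CPE constant, F s^(P-1), > 0.
#' @param pd CPE exponent, in (0, 1\].
#' @return Capacitance in F.
#' @export
dispersed_capacitance <- function(rd, td, pd) {
  stopifnot(is.numeric(rd), is.numeric(td), is.numeric(pd))
  if (any(rd <= 0) || any(td <= 0)) {
    stop("rd and td must be strictly positive", call. = FALSE)
  }
  if (any(pd <= 0) || any(pd > 1)) {
    stop("pd must lie in (0, 1]; the unification exponent 1/pd is singular at 0",
         call. = FALSE)
  }
  (td * rd^(1 - pd))^(1 / pd)
}

#' Total effective capacitance of the circuit
#'
#' The unified capacitance summarising all low-frequency double-layer
#' phenomena of the circuit: the dispersed-medium capacitance
#' [dispersed_capacitance()] sits in parallel with the electrode
#' capacitance, so
#' \deqn{C_{ef} = C_e + \left(T_d R_d^{\,1-P_d}\right)^{1/P_d}.}
#' This single scalar is the response variable used for
#' concentration calibration of suspensions.
#'
#' @param params A [circuit_params()] object, or a named list with at least
#'   `ce` (>= 0), `rd`, `td`, `pd`.
#' @return Effective capacitance in F.
#' @examples
#' p <- circuit_params(0.1, 0.3, 1e-6, 1e4, 1e-6, 0.7)
#' effective_capacitance(p) * 1e6   # in uF
#' @export
effective_capacitance <- function(params) {
  p <- if (inherits(params, "circuit_params")) params else as.list(params)
  if (!all(c("ce", "rd", "td", "pd") %in% names(p))) {
    stop("params must provide ce, rd, td and pd", call. = FALSE)
  }
  if (!is.numeric(p$ce) || p$ce < 0) {
    stop("ce must be non-negative", call. = FALSE)
  }
  p$ce + dispersed_capacitance(p$rd, p$td, p$pd)
}

#' Reference simulation cases
#'
#' The five parameter sets used for the forward-simulation study of how the
#' effective capacitance summarises the spectrum: cases a--c increase the
#' dispersed-medium CPE exponent `pd` (0.7, 0.8, 0.9) at fixed electrode
#' capacitance, cases c--e increase `ce` (1, 2, 4 uF) at fixed `pd`. All
#' share `ts` = 0.1 F s^(P-1), `ps` = 0.3, `rd` = 10 kOhm,
#' `td` = 1e-6 F s^(P-1).
#'
#' @return A data.frame with columns `case`, `ts`, `ps`, `ce`, `rd`, `td`,
#'   `pd` (SI units), one row per case.
#' @examples
#' sapply(split(simulation_cases(), simulation_cases()$case),
#'        effective_capacitance)
#' @export
simulation_cases <- function() {
  data.frame(
    case = c("a", "b", "c", "d", "e"),
    ts = 0.1, ps = 0.3,
    ce = c(1e-6, 1e-6, 1e-6, 2e-6, 4e-6),
    rd = 1e4, td = 1e-6,
    pd = c(0.7, 0.8, 0.9, 0.9, 0.9),
    stringsAsFactors = FALSE
  )
}
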