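#' Proportional noise model for synthetic spectra
#'
#' Multiplicative complex Gaussian noise emulating potentiostat measurement
#' error: each spectrum point is scaled by `1 + eps_re + 1i*eps_im` with
#' independent zero-mean Gaussians of standard deviation `relative_sigma`.
#' Proportional (not additive) noise is appropriate because |Z| spans
#' about a decade over the 10--1000 Hz band and instrument error tracks
#' the signal level. The default 1% sits at the low end of typical
#' replicate-to-replicate spreads for suspension measurements.
#'
#' @param relative_sigma Noise level as a fraction of |Z|, >= 0.
#' @param seed Integer seed making the generator deterministic.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(relative_sigma = 0.01, seed = 1) {
  stopifnot(is.numeric(relative_sigma), length(relative_sigma) == 1,
            relative_sigma >= 0, is.numeric(seed))
  structure(list(relative_sigma = relative_sigma, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic impedance spectrum
#'
#' Evaluates the circuit forward model on a grid and applies the
#' multiplicative complex noise of a [noise_model()]:
#' `Z_obs(f) = Z_model(f) * (1 + eps_re + 1i*eps_im)`. With
#' `relative_sigma = 0` the output equals [circuit_impedance()] exactly;
#' the same seed always reproduces the same spectrum, and the caller's RNG
#' state is left untouched.
#'
#' @param params A [circuit_params()] object.
#' @param frequency_hz Frequency grid (default [log_freq_grid()]).
#' @param noise A [noise_model()].
#' @return An [eis_spectrum()].
#' @export
generate_spectrum <- function(params, frequency_hz = log_freq_grid(),
                              noise = noise_model(0)) {
  stopifnot(inherits(noise, "noise_model"))
  clean <- circuit_impedance(params, frequency_hz)
  if (noise$relative_sigma == 0) return(clean)
  n <- length(clean$z)
  z <- with_seed(noise$seed, {
    eps <- stats::rnorm(n, 0, noise$relative_sigma) +
      1i * stats::rnorm(n, 0, noise$relative_sigma)
    clean$z * (1 + eps)
  })
  eis_spectrum(clean$frequency_hz, z)
}

#' Reference fitted parameter sets for particle suspensions
#'
#' Bundled equivalent-circuit parameter sets for polymer-microsphere
#' suspensions in physiological saline: three particle diameters (6, 15,
#' 48 um) at five concentrations each (25--400 particles/uL). These serve
#' as realistic generators for synthetic-data studies and as ground truth
#' for parameter-recovery tests; the electrode capacitance `ce` rises with
#' concentration within each diameter, which is what makes the effective
#' capacitance a usable concentration response.
#'
#' @return A data.frame with columns `conc_per_ul`, `diameter_um`, `ts`,
#'   `ps`, `ce`, `rd`, `td`, `pd` (SI units), 15 rows.
#' @export
reference_fits <- function() {
  df <- data.frame(
    conc_per_ul = rep(c(25, 50, 100, 200, 400), each = 3),
    diameter_um = rep(c(6, 15, 48), times = 5),
    ts = c(0.86, 1.86, 0.62, 1.54, 1.43, 0.54, 0.89, 8.50, 1.05,
           1.44, 5.18, 0.16, 3.32, 6.63, 0.97) * 1e-3,
    ps = c(0.31, 0.24, 0.36, 0.26, 0.26, 0.37, 0.31, 0.44, 0.30,
           0.27, 0.15, 0.29, 0.19, 0.12, 0.28),
    ce = c(0.57, 0.74, 0.84, 0.62, 0.82, 0.85, 0.66, 0.72, 0.86,
           0.71, 0.76, 0.88, 0.76, 0.77, 0.90) * 1e-6,
    rd = c(3815, 6412, 7284, 3868, 3570, 6753, 3863, 1186, 7078,
           4561, 1741, 7875, 5049, 1827, 10692),
    td = c(9.9, 7.1, 6.9, 9.4, 6.9, 6.7, 9.3, 8.6, 7.2,
           8.2, 8.3, 7.7, 8.0, 8.0, 6.6) * 1e-7,
    pd = c(0.73, 0.74, 0.75, 0.75, 0.71, 0.75, 0.76, 0.80, 0.75,
           0.78, 0.80, 0.76, 0.75, 0.81, 0.74)
  )
  df
}

#' Concentration-to-parameters trend for synthetic series
#'
#' Builds the default monotone map from concentration to circuit
#' parameters for a chosen particle diameter: the electrode capacitance
#' `ce` is interpolated linearly in concentration between the bundled
#' endpoints (lowest and highest concentration rows of
#' [reference_fits()]), while `ts`, `ps`, `rd`, `td`, `pd` are held at the
#' per-diameter medians. Because the dispersed-medium branch is then
#' constant, the effective capacitance is exactly linear in concentration
#' -- the idealized behaviour a calibration assumes.
#'
#' @param diameter_um One of 6, 15, 48.
#' @return A function mapping a concentration (per uL) to a
#'   [circuit_params()] object.
#' @export
ce_trend <- function(diameter_um = 6) {
  ref <- reference_fits()
  rows <- ref[ref$diameter_um == diameter_um, ]
  if (nrow(rows) == 0) {
    stop("no reference rows for diameter ", diameter_um,
         " um; available: ", paste(unique(ref$diameter_um), collapse = ", "),
         call. = FALSE)
  }
  rows <- rows[order(rows$conc_per_ul), ]
  c_lo <- rows$conc_per_ul[1]
  c_hi <- rows$conc_per_ul[nrow(rows)]
  ce_lo <- rows$ce[1]
  ce_hi <- rows$ce[nrow(rows)]
  med <- lapply(rows[c("ts", "ps", "rd", "td", "pd")], stats::median)
  function(conc) {
    ce <- ce_lo + (ce_hi - ce_lo) * (conc - c_lo) / (c_hi - c_lo)
    circuit_params(ts = med$ts, ps = med$ps, ce = ce,
                   rd = med$rd, td = med$td, pd = med$pd)
  }
}

#' Generate a synthetic concentration series
#'
#' One synthetic spectrum per concentration, with parameters supplied by a
#' monotone trend function ([ce_trend()] by default). Per-concentration
#' noise seeds derive deterministically from the noise model's seed, so
#' the whole series is reproducible.
#'
#' @param concentrations Concentrations (per uL), e.g.
#'   `serial_dilution(400, 5, 2)`.
#' @param trend Function mapping concentration to [circuit_params()]; a
#'   trend returning invalid parameters raises the constructor's error.
#' @param frequency_hz Frequency grid shared by all spectra.
#' @param noise A [noise_model()].
#' @return A list with one element per concentration, each a list with
#'   `concentration`, `params` (the generating truth), and `spectrum`.
#' @examples
#' series <- generate_concentration_series(c(25, 100, 400))
#' sapply(series, function(e) effective_capacitance(e$params))
#' @export
generate_concentration_series <- function(concentrations,
                                          trend = ce_trend(6),
                                          frequency_hz = log_freq_grid(),
                                          noise = noise_model(0)) {
  stopifnot(is.numeric(concentrations), length(concentrations) >= 1,
            is.function(trend), inherits(noise, "noise_model"))
  lapply(seq_along(concentrations), function(k) {
    p <- as_circuit_params(trend(concentrations[k]))
    nm <- noise_model(noise$relative_sigma, noise$seed + k - 1L)
    list(concentration = concentrations[k],
         params = p,
         spectrum = generate_spectrum(p, frequency_hz, nm))
  })
}
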