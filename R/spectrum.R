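#' Logarithmically spaced frequency grid
#'
#' Builds the default measurement grid for low-frequency impedance sweeps:
#' points equally spaced in log10(frequency) between `fmin` and `fmax`.
#' The default band, 10--1000 Hz, is where electrode and dispersed-medium
#' double layers dominate the spectrum of an electrolytic suspension
#' (alpha dispersion).
#'
#' @param fmin,fmax Band edges in Hz, both strictly positive, `fmin < fmax`.
#' @param n Number of grid points (>= 2).
#' @return Numeric vector of strictly increasing frequencies in Hz.
#' @examples
#' f <- log_freq_grid()
#' range(f)
#' @export
log_freq_grid <- function(fmin = 10, fmax = 1000, n = 50) {
  stopifnot(is.numeric(fmin), is.numeric(fmax), fmin > 0, fmax > fmin, n >= 2)
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

## Shared grid validation: strictly positive, strictly increasing, finite.
## CPE impedance diverges at f = 0 for P > 0, so zero is rejected outright.
validate_grid <- function(frequency_hz) {
  if (!is.numeric(frequency_hz) || length(frequency_hz) == 0) {
    stop("frequency grid must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(frequency_hz) || any(!is.finite(frequency_hz))) {
    stop("frequency grid contains non-finite values", call. = FALSE)
  }
  if (any(frequency_hz <= 0)) {
    stop("all frequencies must be strictly positive (CPE impedance diverges at 0 Hz)",
         call. = FALSE)
  }
  if (anyDuplicated(frequency_hz)) {
    stop("frequency grid contains duplicated frequencies", call. = FALSE)
  }
  invisible(frequency_hz)
}

#' Complex impedance spectrum
#'
#' Container pairing a frequency grid with one complex impedance value per
#' point. Points are stored sorted by increasing frequency regardless of
#' input order, so downstream computations are invariant to row order.
#'
#' @param frequency_hz Strictly positive frequencies in Hz (duplicates rejected).
#' @param z Complex impedance per point, in Ohm.
#' @return An object of class `"eis_spectrum"` with fields `frequency_hz`
#'   and `z`.
#' @seealso [circuit_impedance()], [read_spectrum()], [magnitude_spectrum()]
#' @examples
#' s <- eis_spectrum(c(10, 100), c(100 - 50i, 80 - 10i))
#' impedance_magnitude(s)
#' @export
eis_spectrum <- function(frequency_hz, z) {
  validate_grid(frequency_hz)
  if (length(z) != length(frequency_hz)) {
    stop("z and frequency_hz must have the same length", call. = FALSE)
  }
  z <- as.complex(z)
  if (anyNA(z)) stop("z contains missing values", call. = FALSE)
  ord <- order(frequency_hz)
  structure(list(frequency_hz = frequency_hz[ord], z = z[ord]),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  n <- length(x$frequency_hz)
  cat(sprintf("Impedance spectrum: %d points, %.4g-%.4g Hz\n",
              n, min(x$frequency_hz), max(x$frequency_hz)))
  cat(sprintf("  |Z| range: %.4g-%.4g Ohm, phase range: %.1f to %.1f deg\n",
              min(Mod(x$z)), max(Mod(x$z)),
              min(impedance_phase(x)), max(impedance_phase(x))))
  invisible(x)
}

#' @export
as.data.frame.eis_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency_hz,
             re_z_ohm = Re(x$z),
             im_z_ohm = Im(x$z))
}

#' Impedance magnitude and phase of a spectrum
#'
#' @param x An `eis_spectrum`.
#' @param units `"deg"` (default, matching Bode-plot convention) or `"rad"`.
#' @return Numeric vector, one value per grid point.
#' @export
impedance_magnitude <- function(x) {
  stopifnot(inherits(x, "eis_spectrum"))
  Mod(x$z)
}

#' @rdname impedance_magnitude
#' @export
impedance_phase <- function(x, units = c("deg", "rad")) {
  stopifnot(inherits(x, "eis_spectrum"))
  units <- match.arg(units)
  ph <- Arg(x$z)
  if (units == "deg") ph * 180 / pi else ph
}

#' Impedance-magnitude spectrum
#'
#' The magnitude-only view used by the dispersed-medium index: a frequency
#' grid with |Z| per point. Build one directly or coerce an `eis_spectrum`
#' with [as_magnitude_spectrum()].
#'
#' @param frequency_hz Strictly positive frequencies in Hz.
#' @param mag_ohm Impedance magnitudes in Ohm, all strictly positive.
#' @return An object of class `"magnitude_spectrum"`.
#' @export
magnitude_spectrum <- function(frequency_hz, mag_ohm) {
  validate_grid(frequency_hz)
  if (length(mag_ohm) != length(frequency_hz)) {
    stop("mag_ohm and frequency_hz must have the same length", call. = FALSE)
  }
  if (!is.numeric(mag_ohm) || anyNA(mag_ohm) || any(mag_ohm <= 0)) {
    stop("all magnitudes must be strictly positive", call. = FALSE)
  }
  ord <- order(frequency_hz)
  structure(list(frequency_hz = frequency_hz[ord], mag_ohm = mag_ohm[ord]),
            class = "magnitude_spectrum")
}

#' @rdname magnitude_spectrum
#' @param x An `eis_spectrum` or `magnitude_spectrum`.
#' @export
as_magnitude_spectrum <- function(x) {
  if (inherits(x, "magnitude_spectrum")) return(x)
  if (inherits(x, "eis_spectrum")) {
    return(magnitude_spectrum(x$frequency_hz, Mod(x$z)))
  }
  stop("cannot coerce object of class '", class(x)[1],
       "' to a magnitude spectrum", call. = FALSE)
}

#' @export
print.magnitude_spectrum <- function(x, ...) {
  cat(sprintf("Magnitude spectrum: %d points, %.4g-%.4g Hz, |Z| %.4g-%.4g Ohm\n",
              length(x$frequency_hz), min(x$frequency_hz), max(x$frequency_hz),
              min(x$mag_ohm), max(x$mag_ohm)))
  invisible(x)
}

#' Average replicate spectra
#'
#' Averages |Z| per frequency across replicate acquisitions (e.g. aliquots
#' of the same suspension) and reports the per-frequency spread as a
#' percentage of the mean. All replicates must share the same grid.
#'
#' @param spectra List of `eis_spectrum` or `magnitude_spectrum` objects on
#'   identical grids.
#' @return A `magnitude_spectrum` of per-frequency means, with attribute
#'   `"sd_percent"` giving 100 * sd/mean per frequency (zero for a single
#'   replicate).
#' @export
average_spectra <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  mags <- lapply(spectra, as_magnitude_spectrum)
  f <- mags[[1]]$frequency_hz
  for (m in mags[-1]) {
    if (length(m$frequency_hz) != length(f) ||
        any(abs(m$frequency_hz - f) > 1e-9 * f)) {
      stop("replicate spectra must share an identical frequency grid",
           call. = FALSE)
    }
  }
  mat <- vapply(mags, function(m) m$mag_ohm, numeric(length(f)))
  mat <- matrix(mat, nrow = length(f))
  mu <- rowMeans(mat)
  sd_pct <- if (ncol(mat) > 1) 100 * apply(mat, 1, stats::sd) / mu else rep(0, length(f))
  out <- magnitude_spectrum(f, mu)
  attr(out, "sd_percent") <- sd_pct
  out
}
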