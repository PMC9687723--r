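#' Dispersed medium index spectrum
#'
#' Normalizes a suspension's impedance-magnitude spectrum against the pure
#' liquid medium measured in the same cell:
#' \deqn{DMi(f) = \frac{|Z|_S(f) - |Z|_{LM}(f)}{|Z|_{LM}(f)},}
#' pointwise per frequency. The liquid medium itself maps to 0 everywhere;
#' values are bounded below by -1 since magnitudes are positive. The index
#' is invariant under a common rescaling of both spectra, so gain errors
#' shared by the two measurements cancel.
#'
#' @param suspension,liquid_medium `eis_spectrum` or `magnitude_spectrum`
#'   objects. Grids must be identical unless `interpolate = TRUE`, in which
#'   case the medium is interpolated (linearly in log-frequency) onto the
#'   suspension grid over the overlapping range.
#' @param interpolate Allow grid mismatch via log-frequency interpolation
#'   (default `FALSE`; frequency sweeps from the same instrument are
#'   nominally identical).
#' @return An object of class `"dmi_spectrum"` with fields `frequency_hz`
#'   and `dmi`.
#' @seealso [dmi_at()], [average_spectra()]
#' @examples
#' f <- log_freq_grid(n = 10)
#' lm_ <- magnitude_spectrum(f, rep(1000, 10))
#' s <- magnitude_spectrum(f, rep(1200, 10))
#' compute_dmi(s, lm_)$dmi   # 0.2 everywhere
#' @export
compute_dmi <- function(suspension, liquid_medium, interpolate = FALSE) {
  s <- as_magnitude_spectrum(suspension)
  m <- as_magnitude_spectrum(liquid_medium)
  same <- length(s$frequency_hz) == length(m$frequency_hz) &&
    all(abs(s$frequency_hz - m$frequency_hz) <= 1e-9 * s$frequency_hz)
  if (same) {
    f <- s$frequency_hz
    mag_m <- m$mag_ohm
    mag_s <- s$mag_ohm
  } else if (!interpolate) {
    stop("frequency grids differ; rerun with interpolate = TRUE to resample ",
         "the liquid medium onto the suspension grid", call. = FALSE)
  } else {
    keep <- s$frequency_hz >= min(m$frequency_hz) &
      s$frequency_hz <= max(m$frequency_hz)
    if (!any(keep)) {
      stop("frequency grids do not overlap", call. = FALSE)
    }
    f <- s$frequency_hz[keep]
    mag_s <- s$mag_ohm[keep]
    mag_m <- stats::approx(log(m$frequency_hz), m$mag_ohm, xout = log(f))$y
  }
  structure(list(frequency_hz = f, dmi = (mag_s - mag_m) / mag_m),
            class = "dmi_spectrum")
}

#' @export
print.dmi_spectrum <- function(x, ...) {
  cat(sprintf("DMi spectrum: %d points, %.4g-%.4g Hz, DMi %.3g to %.3g\n",
              length(x$frequency_hz), min(x$frequency_hz),
              max(x$frequency_hz), min(x$dmi), max(x$dmi)))
  invisible(x)
}

#' @export
as.data.frame.dmi_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency_hz, dmi = x$dmi)
}

#' Dispersed medium index at a single frequency
#'
#' Extracts the scalar DMi used for concentration calibration (typically at
#' 50 Hz, where suspensions separate most clearly). If the requested
#' frequency coincides with a grid point the stored value is returned; an
#' off-grid frequency inside the sweep range is interpolated linearly in
#' log-frequency and the result carries attribute `interpolated = TRUE`.
#'
#' @param dmi A `dmi_spectrum`.
#' @param frequency_hz Query frequency, inside the grid range.
#' @return The DMi scalar; attribute `"interpolated"` records whether
#'   interpolation was needed.
#' @export
dmi_at <- function(dmi, frequency_hz) {
  stopifnot(inherits(dmi, "dmi_spectrum"))
  if (!is.numeric(frequency_hz) || length(frequency_hz) != 1 ||
      !is.finite(frequency_hz)) {
    stop("frequency_hz must be a single finite number", call. = FALSE)
  }
  f <- dmi$frequency_hz
  if (frequency_hz < min(f) || frequency_hz > max(f)) {
    stop(sprintf("frequency %.4g Hz is outside the measured range %.4g-%.4g Hz",
                 frequency_hz, min(f), max(f)), call. = FALSE)
  }
  hit <- which(abs(f - frequency_hz) <= 1e-9 * frequency_hz)
  if (length(hit) > 0) {
    out <- dmi$dmi[hit[1]]
    attr(out, "interpolated") <- FALSE
  } else {
    out <- stats::approx(log(f), dmi$dmi, xout = log(frequency_hz))$y
    attr(out, "interpolated") <- TRUE
  }
  out
}
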