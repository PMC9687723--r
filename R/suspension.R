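#' Suspension description
#'
#' Bookkeeping record for a monodisperse suspension of spherical particles
#' (or cells, taking their reported diameter): particle diameter,
#' concentration, and the measured sample volume.
#'
#' @param diameter_um Particle diameter in micrometres, > 0.
#' @param concentration_per_ul Particles per microlitre, >= 0.
#' @param sample_volume_ul Sample (chamber) volume in microlitres, > 0.
#' @return An object of class `"suspension_spec"`.
#' @examples
#' suspension_spec(6, 25, 100)
#' @export
suspension_spec <- function(diameter_um, concentration_per_ul,
                            sample_volume_ul = 100) {
  vals <- c(diameter_um, concentration_per_ul, sample_volume_ul)
  if (!is.numeric(vals) || length(vals) != 3 || any(!is.finite(vals))) {
    stop("all suspension fields must be finite numbers", call. = FALSE)
  }
  if (diameter_um <= 0 || sample_volume_ul <= 0) {
    stop("diameter_um and sample_volume_ul must be strictly positive",
         call. = FALSE)
  }
  if (concentration_per_ul < 0) {
    stop("concentration_per_ul must be non-negative", call. = FALSE)
  }
  structure(list(diameter_um = diameter_um,
                 concentration_per_ul = concentration_per_ul,
                 sample_volume_ul = sample_volume_ul),
            class = "suspension_spec")
}

#' @export
print.suspension_spec <- function(x, ...) {
  cat(sprintf("Suspension: %.3g um spheres, %.4g /uL in %.4g uL (Vf = %.3g)\n",
              x$diameter_um, x$concentration_per_ul, x$sample_volume_ul,
              volume_fraction(x)))
  invisible(x)
}

#' Volume fraction of a suspension
#'
#' Fraction of the suspension volume occupied by the dispersed phase,
#' modelling particles as perfect spheres:
#' \deqn{V_f = c \cdot \frac{\pi}{6} d^3 / 10^9,}
#' with `c` in particles/uL, `d` in um, and 1 uL = 1e9 um^3. Independent of
#' the sample volume; linear in concentration, cubic in diameter.
#'
#' @param s A [suspension_spec()].
#' @return Dimensionless volume fraction.
#' @examples
#' volume_fraction(suspension_spec(6, 25))    # ~3e-6
#' @export
volume_fraction <- function(s) {
  stopifnot(inherits(s, "suspension_spec"))
  s$concentration_per_ul * (pi / 6) * s$diameter_um^3 / 1e9
}

#' Total particle count in the measured sample
#'
#' @param s A [suspension_spec()].
#' @return Concentration times sample volume, rounded to the nearest whole
#'   particle.
#' @examples
#' particle_count(suspension_spec(6, 25, 100))  # 2500
#' @export
particle_count <- function(s) {
  stopifnot(inherits(s, "suspension_spec"))
  round(s$concentration_per_ul * s$sample_volume_ul)
}

#' Serial dilution series
#'
#' Concentrations obtained by repeated dilution by a fixed factor, starting
#' from a stock. The standard preparation for calibration series, e.g.
#' half-fold dilution of a 400 /uL stock giving 400, 200, 100, 50, 25 /uL.
#'
#' @param start_per_ul Stock concentration, > 0.
#' @param n_steps Number of concentrations in the series (>= 1).
#' @param factor Dilution factor between consecutive steps, > 1.
#' @return Descending geometric series of length `n_steps`, first element
#'   equal to `start_per_ul`.
#' @examples
#' serial_dilution(400, 5, 2)
#' @export
serial_dilution <- function(start_per_ul, n_steps, factor = 2) {
  stopifnot(is.numeric(start_per_ul), start_per_ul > 0)
  if (!is.numeric(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(factor) || factor <= 1) {
    stop("dilution factor must be greater than 1", call. = FALSE)
  }
  start_per_ul / factor^(seq_len(n_steps) - 1)
}
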