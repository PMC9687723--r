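#' Read an impedance spectrum from CSV
#'
#' Reads a frequency sweep in either of two self-describing dialects,
#' auto-detected from the header line:
#' * rectangular: `frequency_hz,re_z_ohm,im_z_ohm`
#' * polar: `frequency_hz,mag_z_ohm,phase_deg` (converted via
#'   `Z = mag * (cos(theta) + 1i*sin(theta))`, theta in degrees)
#'
#' Rows are sorted by frequency on load. Unknown headers, non-numeric
#' cells, non-positive frequencies and duplicated frequencies are rejected
#' with the offending file line number.
#'
#' @param path Path to a CSV file.
#' @return An [eis_spectrum()].
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- gsub("[[:space:]\"]", "", readLines(path, n = 1))
  dialect <- switch(header,
    "frequency_hz,re_z_ohm,im_z_ohm" = "rectangular",
    "frequency_hz,mag_z_ohm,phase_deg" = "polar",
    stop("unrecognized header '", header, "' in ", path,
         "; expected 'frequency_hz,re_z_ohm,im_z_ohm' or ",
         "'frequency_hz,mag_z_ohm,phase_deg'", call. = FALSE)
  )
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d of %s",
                   df[bad[1], j], names(df)[j], bad[1] + 1L, path),
           call. = FALSE)
    }
  }
  f <- num[[1]]
  bad <- which(f <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive frequency %g at line %d of %s",
                 f[bad[1]], bad[1] + 1L, path), call. = FALSE)
  }
  dup <- which(duplicated(f))
  if (length(dup) > 0) {
    stop(sprintf("duplicated frequency %g at line %d of %s",
                 f[dup[1]], dup[1] + 1L, path), call. = FALSE)
  }
  z <- if (dialect == "rectangular") {
    complex(real = num[[2]], imaginary = num[[3]])
  } else {
    theta <- num[[3]] * pi / 180
    num[[2]] * complex(real = cos(theta), imaginary = sin(theta))
  }
  eis_spectrum(f, z)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write an impedance spectrum to CSV
#'
#' Exports in one of three table layouts: `"rectangular"`
#' (`frequency_hz,re_z_ohm,im_z_ohm`; lossless, round-trips through
#' [read_spectrum()]), `"polar"` (`frequency_hz,mag_z_ohm,phase_deg`), or
#' `"nyquist"` (`re_z_ohm,neg_im_z_ohm`, the plotting convention with
#' frequency implicit).
#'
#' @param x An [eis_spectrum()].
#' @param path Output path.
#' @param format Output dialect.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path,
                           format = c("rectangular", "polar", "nyquist")) {
  stopifnot(inherits(x, "eis_spectrum"))
  format <- match.arg(format)
  lines <- switch(format,
    rectangular = c("frequency_hz,re_z_ohm,im_z_ohm",
                    paste(fmt_num(x$frequency_hz), fmt_num(Re(x$z)),
                          fmt_num(Im(x$z)), sep = ",")),
    polar = c("frequency_hz,mag_z_ohm,phase_deg",
              paste(fmt_num(x$frequency_hz), fmt_num(Mod(x$z)),
                    fmt_num(Arg(x$z) * 180 / pi), sep = ",")),
    nyquist = c("re_z_ohm,neg_im_z_ohm",
                paste(fmt_num(Re(x$z)), fmt_num(-Im(x$z)), sep = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a DMi spectrum to CSV
#'
#' @param x A `dmi_spectrum`.
#' @param path Output path; header `frequency_hz,dmi`.
#' @return `path`, invisibly.
#' @export
write_dmi <- function(x, path) {
  stopifnot(inherits(x, "dmi_spectrum"))
  writeLines(c("frequency_hz,dmi",
               paste(fmt_num(x$frequency_hz), fmt_num(x$dmi), sep = ",")),
             path)
  invisible(path)
}

report_payload <- function(x) {
  if (inherits(x, "circuit_fit")) {
    list(
      schema_version = "1",
      type = "circuit_fit",
      params = list(ts = x$params$ts, ps = x$params$ps, ce = x$params$ce,
                    rd = x$params$rd, td = x$params$td, pd = x$params$pd),
      cef_F = x$cef,
      cef_uF = round(x$cef * 1e6, 1),
      cost = x$cost,
      converged = x$converged,
      n_evaluations = x$n_evaluations,
      start_index = x$start_index,
      weighting = x$weighting
    )
  } else if (inherits(x, "calibration_curve")) {
    list(
      schema_version = "1",
      type = "calibration_curve",
      slope = x$slope,
      intercept = x$intercept,
      r_squared = x$r_squared,
      n = x$n,
      conc_min = min(x$concentrations),
      conc_max = max(x$concentrations),
      log_concentration = x$log_concentration
    )
  } else if (is.list(x) && identical(x$schema_version, "1")) {
    x  # already a parsed report; re-serialize as-is
  } else {
    stop("write_report expects a circuit_fit, calibration_curve, or a ",
         "parsed report list", call. = FALSE)
  }
}

#' Write a machine-readable JSON report
#'
#' Serializes a fit or calibration result to JSON with a stable key order,
#' SI values plus display units (uF, one decimal), and a schema version.
#' Writing a report parsed back with [read_report()] reproduces the file
#' byte for byte.
#'
#' @param x A `circuit_fit`, `calibration_curve`, or parsed report list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  payload <- report_payload(x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
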