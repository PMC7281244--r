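#' Beamline geometry metadata
#'
#' Minimal instrument description used for angle-to-Q conversion.
#'
#' @param wavelength X-ray wavelength \eqn{\lambda}, \eqn{\mathrm{\AA}};
#'   default 1.54 (Cu K-alpha / the synchrotron setting used throughout).
#' @param sample_detector_distance Sample-to-detector distance in metres
#'   (metadata only; not used in the conversion).
#' @return An object of class `"instrument_config"`.
#' @examples
#' instrument_config()
#' @export
instrument_config <- function(wavelength = 1.54,
                              sample_detector_distance = NA_real_) {
  wavelength <- as.numeric(wavelength)[1L]
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("'wavelength' must be a positive number (Angstrom)")
  structure(list(wavelength = wavelength,
                 sample_detector_distance = as.numeric(sample_detector_distance)[1L]),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf("Instrument: lambda = %.4g A, sample-detector distance = %s m\n",
              x$wavelength,
              if (is.finite(x$sample_detector_distance))
                format(x$sample_detector_distance) else "unset"))
  invisible(x)
}

#' Momentum transfer from scattering angle
#'
#' \eqn{Q = 4\pi \sin\theta / \lambda} with \eqn{2\theta} the scattering
#' angle.
#'
#' @param two_theta Scattering angle \eqn{2\theta} in radians, in
#'   \eqn{[0, \pi)}. Vectorised.
#' @param instrument An [instrument_config()].
#' @return Momentum transfer in \eqn{\mathrm{\AA}^{-1}}.
#' @examples
#' q_from_angle(0.02, instrument_config(wavelength = 1.54))
#' @export
q_from_angle <- function(two_theta, instrument = instrument_config()) {
  stopifnot(inherits(instrument, "instrument_config"))
  two_theta <- as.numeric(two_theta)
  if (any(!is.finite(two_theta)) || any(two_theta < 0) ||
      any(two_theta >= pi))
    stop("'two_theta' must lie in [0, pi) radians")
  4 * pi * sin(two_theta / 2) / instrument$wavelength
}

#' Read a 3-column ASCII SAXS file
#'
#' Reads the common beamline-reduction dialect: whitespace-separated numeric
#' columns Q (\eqn{\mathrm{\AA}^{-1}}), intensity (\eqn{cm^{-1}}) and an
#' optional third uncertainty column; `#` starts a comment. Rows are sorted
#' by Q (with a warning) when the file is not already increasing.
#'
#' @param path File path.
#' @param q_unit Either `"A^-1"` (default) or `"nm^-1"`; nm^-1 input is
#'   converted to \eqn{\mathrm{\AA}^{-1}} on read.
#' @return A [saxs_curve()] labelled with the file name.
#' @export
read_saxs_dat <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stop("no data rows in ", path)
  rows <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L || !(ncol %in% c(2L, 3L))) {
    bad <- keep[which(lengths(rows) != lengths(rows)[1L])[1L]]
    stop("expected 2 or 3 numeric columns in ", path,
         if (length(ncol) > 1L) paste0(" (first irregular row: line ", bad, ")"))
  }
  vals <- suppressWarnings(vapply(rows, function(r) as.numeric(r),
                                  numeric(ncol)))
  if (ncol == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(apply(vals, 2L, function(v) any(is.na(v))))
  if (length(bad))
    stop("non-numeric row in ", path, " at line ", keep[bad[1L]])
  m <- t(vals)
  if (q_unit == "nm^-1") m[, 1L] <- m[, 1L] / 10
  if (is.unsorted(m[, 1L], strictly = TRUE)) {
    warning("Q column not strictly increasing in ", path, "; sorting")
    m <- m[order(m[, 1L]), , drop = FALSE]
    m <- m[!duplicated(m[, 1L]), , drop = FALSE]
  }
  saxs_curve(m[, 1L], m[, 2L],
             sigma = if (ncol == 3L) m[, 3L] else NULL,
             label = basename(path))
}

#' Write a scattering curve as 3-column ASCII
#'
#' @param curve A [saxs_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c(
    paste0("# ", if (nzchar(curve$label)) curve$label else "SAXS curve"),
    "# Q [A^-1]  I [cm^-1]" ,
    if (!is.null(curve$sigma)) "# third column: 1-sigma uncertainty [cm^-1]"
  )
  m <- cbind(curve$q, curve$intensity,
             if (!is.null(curve$sigma)) curve$sigma)
  body <- apply(m, 1L, function(r)
    paste(formatC(r, format = "e", digits = 9), collapse = "  "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
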