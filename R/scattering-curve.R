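#' One-dimensional SAXS profile
#'
#' Container for a reduced small-angle X-ray scattering curve: the momentum
#' transfer grid Q (\eqn{\mathrm{\AA}^{-1}}), the absolute-scale differential
#' cross section \eqn{d\Sigma/d\Omega(Q)} (\eqn{cm^{-1}}) and, optionally, a
#' per-point 1-sigma counting uncertainty.
#'
#' @param q Numeric vector of momentum transfer values, strictly increasing,
#'   all positive, in \eqn{\mathrm{\AA}^{-1}}.
#' @param intensity Numeric vector of intensities, \eqn{cm^{-1}}, finite,
#'   same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties,
#'   \eqn{cm^{-1}}, all positive, same length as `q`. `NULL` when unknown.
#' @param label Free-text label carried through plots and file headers.
#'
#' @return An object of class `"saxs_curve"`: a list with elements `q`,
#'   `intensity`, `sigma` and `label`.
#' @examples
#' q <- seq(0.01, 0.3, length.out = 50)
#' crv <- saxs_curve(q, exp(-q^2 * 256 / 3))
#' crv
#' @export
saxs_curve <- function(q, intensity, sigma = NULL, label = "") {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) == 0L) stop("'q' must be non-empty")
  if (length(q) != length(intensity))
    stop("'q' and 'intensity' must have the same length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("'q' must be finite and strictly positive")
  if (any(diff(q) <= 0)) stop("'q' must be strictly increasing")
  if (any(!is.finite(intensity))) stop("'intensity' must be finite")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("'sigma' must have the same length as 'q'")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("'sigma' must be finite and strictly positive")
  }
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = as.character(label)[1L]),
    class = "saxs_curve"
  )
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat("SAXS curve", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n")
  cat(sprintf("  %d points, Q in [%.4g, %.4g] A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  I(Q) in [%.4g, %.4g] cm^-1, uncertainties %s\n",
              min(x$intensity), max(x$intensity),
              if (is.null(x$sigma)) "absent" else "present"))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' @export
as.data.frame.saxs_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' @export
plot.saxs_curve <- function(x, log = "xy", ...) {
  ok <- x$intensity > 0 | !grepl("y", log)
  graphics::plot(x$q[ok], x$intensity[ok], log = log,
                 xlab = expression(Q ~ (ring(A)^-1)),
                 ylab = expression(d * Sigma / d * Omega ~ (cm^-1)),
                 main = x$label, ...)
  invisible(x)
}

#' Kratky transform of a scattering curve
#'
#' Computes \eqn{(Q, Q^2 I(Q))}. In this representation compact globular
#' particles produce a bell-shaped peak while flexible chains plateau at
#' high Q, which is the basis of the shape classification in
#' [kratky_shape_score()].
#'
#' @param curve A [saxs_curve()].
#' @return A data frame with columns `q` (\eqn{\mathrm{\AA}^{-1}}) and
#'   `q2i` (\eqn{cm^{-1}\,\mathrm{\AA}^{-2}}).
#' @examples
#' crv <- saxs_curve(seq(0.01, 0.5, 0.01), rep(1, 50))
#' head(kratky_transform(crv))
#' @export
kratky_transform <- function(curve) {
  stopifnot(inherits(curve, "saxs_curve"))
  data.frame(q = curve$q, q2i = curve$q^2 * curve$intensity)
}
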