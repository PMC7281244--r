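# Far-UV circular dichroism band-shape analysis. Native (alpha+beta)
# lysozyme shows two negative bands at 208 and 222 nm; conversion to
# beta-sheet-rich amyloid collapses them into a single negative band near
# 215 nm. Classification here is band-shape based (no secondary-structure
# deconvolution).

#' Circular dichroism spectrum
#'
#' @param wavelength Wavelength grid, nm, strictly increasing, within
#'   `[185, 265]`.
#' @param signal Ellipticity, millidegrees, finite.
#' @param n_scans_averaged Number of instrument scans averaged (metadata).
#' @return An object of class `"cd_spectrum"`.
#' @export
cd_spectrum <- function(wavelength, signal, n_scans_averaged = 1L) {
  wavelength <- as.numeric(wavelength)
  signal <- as.numeric(signal)
  if (length(wavelength) != length(signal))
    stop("'wavelength' and 'signal' must have the same length")
  if (any(diff(wavelength) <= 0))
    stop("'wavelength' must be strictly increasing")
  if (min(wavelength) < 185 || max(wavelength) > 265)
    stop("far-UV CD grid must lie within [185, 265] nm")
  if (any(!is.finite(signal))) stop("'signal' must be finite")
  structure(list(wavelength = wavelength, signal = signal,
                 n_scans_averaged = as.integer(n_scans_averaged)),
            class = "cd_spectrum")
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("CD spectrum: %d points, %g-%g nm, signal in [%.3g, %.3g] mdeg\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' @export
plot.cd_spectrum <- function(x, ...) {
  graphics::plot(x$wavelength, x$signal, type = "l",
                 xlab = "wavelength (nm)", ylab = "ellipticity (mdeg)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Baseline subtraction and spline smoothing
#'
#' Subtracts the buffer baseline (interpolated onto the sample grid) and
#' smooths the result with a natural smoothing spline
#' ([stats::smooth.spline()]). `smoothing = 0` skips the spline entirely,
#' so a zero baseline with zero smoothing is the identity.
#'
#' @param raw A [cd_spectrum()].
#' @param buffer_baseline Optional [cd_spectrum()] of the buffer; its grid
#'   must overlap the sample grid.
#' @param smoothing Smoothing strength, the `spar` argument of
#'   [stats::smooth.spline()] in `[0, 1]`; default 0.5.
#' @return A smoothed, baseline-corrected [cd_spectrum()].
#' @export
cd_preprocess <- function(raw, buffer_baseline = NULL, smoothing = 0.5) {
  stopifnot(inherits(raw, "cd_spectrum"))
  wl <- raw$wavelength
  sig <- raw$signal
  if (!is.null(buffer_baseline)) {
    stopifnot(inherits(buffer_baseline, "cd_spectrum"))
    bw <- buffer_baseline$wavelength
    if (max(bw) < min(wl) || min(bw) > max(wl))
      stop("buffer baseline grid does not overlap the sample grid")
    base <- stats::approx(bw, buffer_baseline$signal, wl, rule = 2)$y
    sig <- sig - base
  }
  if (smoothing > 0) {
    fit <- stats::smooth.spline(wl, sig, spar = smoothing)
    sig <- stats::predict(fit, wl)$y
  }
  cd_spectrum(wl, sig, n_scans_averaged = raw$n_scans_averaged)
}

# Topographic prominence of peaks in a numeric sequence: for each local
# maximum, the drop to the highest of the two key saddles separating it
# from higher ground (or from the sequence ends).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    lefts <- y[seq_len(p)]
    higher_l <- which(lefts[seq_len(p - 1)] > y[p])
    sad_l <- if (length(higher_l)) min(y[max(higher_l):p]) else min(lefts)
    rights <- y[p:length(y)]
    higher_r <- which(rights[-1L] > y[p])
    sad_r <- if (length(higher_r))
      min(y[p:(p + min(higher_r))]) else min(rights)
    y[p] - max(sad_l, sad_r)
  }, numeric(1L))
}

#' Locate negative CD minima
#'
#' Finds all local minima with negative ellipticity in a (smoothed)
#' spectrum, suppressing shoulders whose topographic prominence is below
#' `prominence` times that of the deepest minimum.
#'
#' @param spectrum A [cd_spectrum()] (smooth it first with
#'   [cd_preprocess()] on noisy data).
#' @param prominence Relative prominence threshold (default 0.05).
#' @return Data frame with columns `wavelength` (nm, sorted) and `depth`
#'   (mdeg, negative); zero rows when there is no negative minimum.
#' @export
locate_minima <- function(spectrum, prominence = 0.05) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  y <- -spectrum$signal          # minima become peaks
  n <- length(y)
  if (n < 3L) return(data.frame(wavelength = numeric(0), depth = numeric(0)))
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[y[idx] > 0]          # only negative-signal minima
  if (!length(idx))
    return(data.frame(wavelength = numeric(0), depth = numeric(0)))
  prom <- peak_prominence(y, idx)
  keep <- prom >= prominence * max(prom)
  idx <- idx[keep]
  data.frame(wavelength = spectrum$wavelength[idx],
             depth = spectrum$signal[idx])
}

#' Classify a CD spectrum as native-like or beta-rich
#'
#' Band-shape classification: `"native_like"` when negative minima are
#' present in both the 208-nm window (`[204, 212]`) and the 222-nm window
#' (`[218, 226]`); `"beta_rich"` when there is exactly one minimum in
#' `[210, 222]` (the collapsed ~215 nm amyloid band) and no native pair;
#' `"indeterminate"` otherwise (e.g. a flat spectrum). The score is the
#' depth-weighted margin: the fraction of total minima depth carried by
#' the minima supporting the assigned label (0 for indeterminate).
#' Classification is invariant under positive rescaling of the signal.
#'
#' @param spectrum A (smoothed) [cd_spectrum()].
#' @param prominence Passed to [locate_minima()].
#' @return A list with `label`, `score` and `minima` (the data frame from
#'   [locate_minima()]).
#' @export
classify_state <- function(spectrum, prominence = 0.05) {
  mins <- locate_minima(spectrum, prominence)
  total_depth <- sum(abs(mins$depth))
  in_win <- function(lo, hi) mins$wavelength >= lo & mins$wavelength <= hi
  native_pair <- any(in_win(204, 212)) && any(in_win(218, 226))
  beta_single <- sum(in_win(210, 222)) == 1L
  if (nrow(mins) == 0L || total_depth == 0) {
    label <- "indeterminate"; score <- 0
  } else if (native_pair) {
    label <- "native_like"
    score <- sum(abs(mins$depth[in_win(204, 212) | in_win(218, 226)])) /
      total_depth
  } else if (beta_single) {
    label <- "beta_rich"
    score <- sum(abs(mins$depth[in_win(210, 222)])) / total_depth
  } else {
    label <- "indeterminate"; score <- 0
  }
  list(label = label, score = score, minima = mins)
}

#' @rdname read_spectra_csv
#' @export
read_cd_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "mdeg") %in% names(d)))
    stop("expected columns wavelength_nm, mdeg in ", path)
  d <- d[order(d$wavelength_nm), ]
  cd_spectrum(d$wavelength_nm, d$mdeg)
}

#' @rdname read_spectra_csv
#' @param spectrum A [cd_spectrum()].
#' @export
write_cd_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  utils::write.csv(data.frame(wavelength_nm = spectrum$wavelength,
                              mdeg = spectrum$signal),
                   path, row.names = FALSE)
  invisible(path)
}
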