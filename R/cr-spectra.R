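# Congo Red UV/Vis analysis. Bound CR (beta-sheet amyloid) absorbs near
# 538-540 nm, free CR near 505 nm; the 538/505 intensity ratio tracks the
# relative amount of beta structure in solution.

#' UV/Vis absorbance spectrum
#'
#' @param wavelength Wavelength grid, nm, strictly increasing.
#' @param absorbance Absorbance, AU, finite.
#' @param time_label Optional time since induction, minutes.
#' @param replicate Optional replicate identifier.
#' @return An object of class `"absorbance_spectrum"`.
#' @export
absorbance_spectrum <- function(wavelength, absorbance, time_label = NULL,
                                replicate = NULL) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance))
    stop("'wavelength' and 'absorbance' must have the same length")
  if (any(diff(wavelength) <= 0))
    stop("'wavelength' must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("'absorbance' must be finite")
  structure(list(wavelength = wavelength, absorbance = absorbance,
                 time_label = time_label, replicate = replicate),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("Absorbance spectrum: %d points, %g-%g nm%s\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              if (!is.null(x$time_label))
                sprintf(", t = %g min", x$time_label) else ""))
  invisible(x)
}

interp_at <- function(spectrum, nm) {
  if (nm < min(spectrum$wavelength) || nm > max(spectrum$wavelength))
    stop(sprintf("wavelength %g nm outside the measured grid [%g, %g]",
                 nm, min(spectrum$wavelength), max(spectrum$wavelength)))
  stats::approx(spectrum$wavelength, spectrum$absorbance, nm)$y
}

#' Congo Red bound/free intensity ratio
#'
#' The ratio of the absorbance at the bound-CR wavelength (538 nm, the
#' maximum of CR complexed with beta-sheet fibrils) to the absorbance at
#' the free-dye wavelength (505 nm), evaluated by linear interpolation at
#' the exact wavelengths. The ratio is a semi-quantitative proxy for the
#' relative amount of beta structure; it is dilution-invariant and, on
#' two-band spectra, strictly increasing in the bound-dye fraction.
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param bound_nm Bound-dye wavelength, nm (default 538).
#' @param free_nm Free-dye wavelength, nm (default 505).
#' @return The ratio (numeric scalar) with attributes `bound` and `free`
#'   holding the two interpolated intensities.
#' @examples
#' wl <- 400:650
#' sp <- absorbance_spectrum(wl, exp(-(wl - 505)^2 / (2 * 19^2)))
#' beta_ratio(sp)
#' @export
beta_ratio <- function(spectrum, bound_nm = 538, free_nm = 505) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  bound <- interp_at(spectrum, bound_nm)
  free <- interp_at(spectrum, free_nm)
  if (!is.finite(free) || free <= 0)
    stop("free-dye intensity at ", free_nm, " nm is not positive")
  structure(bound / free, bound = bound, free = free)
}

gaussian_band <- function(wl, amp, center, sd) {
  amp * exp(-(wl - center)^2 / (2 * sd^2))
}

#' Two-band area ratio with intensity-ratio equivalence check
#'
#' Decomposes a CR spectrum into two Gaussian bands (centres initialised at
#' the free-dye and bound-dye positions, widths and amplitudes free),
#' integrates each band analytically and returns the bound/free area ratio
#' together with the plain intensity ratio from [beta_ratio()]. On
#' well-behaved two-band spectra the two ratios agree within the
#' experimental error, which is what licenses using the cheaper intensity
#' ratio as the kinetic observable.
#'
#' @param spectrum An [absorbance_spectrum()].
#' @param centers Initial band centres, nm (default `c(505, 540)`).
#' @param bound_nm,free_nm Wavelengths for the raw composite-spectrum
#'   ratio reported alongside (see [beta_ratio()]).
#' @return A list with `area_ratio` (bound/free band areas),
#'   `intensity_ratio` (bound/free fitted peak intensities, i.e. band
#'   amplitudes), `relative_diff` (`area_ratio/intensity_ratio - 1`, `NA`
#'   when the bound band vanishes), `raw_ratio` (the composite 538/505
#'   ratio) and `bands` (data frame of fitted amplitude, centre, sd,
#'   area).
#' @export
area_ratio <- function(spectrum, centers = c(505, 540), bound_nm = 538,
                       free_nm = 505) {
  stopifnot(inherits(spectrum, "absorbance_spectrum"))
  wl <- spectrum$wavelength
  ab <- spectrum$absorbance
  a0 <- vapply(centers, function(cc) max(interp_at(spectrum, cc), 0),
               numeric(1L))
  par0 <- c(a1 = a0[1L], c1 = centers[1L], s1 = 19,
            a2 = a0[2L], c2 = centers[2L], s2 = 23)
  lower <- c(0, centers[1L] - 25, 5, 0, centers[2L] - 25, 5)
  upper <- c(10 * max(ab, 1e-12), centers[1L] + 25, 60,
             10 * max(ab, 1e-12), centers[2L] + 25, 60)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) ab - gaussian_band(wl, p[1L], p[2L], p[3L]) -
      gaussian_band(wl, p[4L], p[5L], p[6L]),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!(fit$info %in% 1:4))
    stop("two-band decomposition did not converge: ", fit$message)
  p <- fit$par
  areas <- c(p[["a1"]] * p[["s1"]], p[["a2"]] * p[["s2"]]) * sqrt(2 * pi)
  if (areas[1L] <= 0)
    stop("free-dye band area is not positive; decomposition unusable")
  ar <- areas[2L] / areas[1L]
  ir <- p[["a2"]] / p[["a1"]]
  list(area_ratio = ar,
       intensity_ratio = ir,
       relative_diff = if (ir > 0) ar / ir - 1 else NA_real_,
       raw_ratio = as.numeric(beta_ratio(spectrum, bound_nm, free_nm)),
       bands = data.frame(band = c("free", "bound"),
                          amplitude = c(p[["a1"]], p[["a2"]]),
                          center = c(p[["c1"]], p[["c2"]]),
                          sd = c(p[["s1"]], p[["s2"]]),
                          area = areas))
}

#' Beta-ratio time course
#'
#' Container for a fibrillation kinetic trace: the CR bound/free ratio as a
#' function of time, with the standard error over replicate measurements
#' when available.
#'
#' @param time Time since induction, minutes, non-decreasing.
#' @param beta_ratio Ratio values, non-negative.
#' @param sem Optional standard errors (same length).
#' @param n_replicates Optional replicate counts per time point.
#' @param label Condition label.
#' @return An object of class `"kinetic_trace"`.
#' @export
kinetic_trace <- function(time, beta_ratio, sem = NULL, n_replicates = NULL,
                          label = "") {
  time <- as.numeric(time)
  beta_ratio <- as.numeric(beta_ratio)
  if (length(time) != length(beta_ratio))
    stop("'time' and 'beta_ratio' must have the same length")
  if (any(diff(time) < 0)) stop("'time' must be non-decreasing")
  if (any(beta_ratio < 0)) stop("'beta_ratio' must be non-negative")
  if (!is.null(sem) && length(sem) != length(time))
    stop("'sem' must match 'time' in length")
  structure(list(time = time, beta_ratio = beta_ratio, sem = sem,
                 n_replicates = n_replicates,
                 label = as.character(label)[1L]),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("Kinetic trace%s: %d time points, t in [%g, %g] min, ratio in [%.3g, %.3g]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$time), min(x$time), max(x$time),
              min(x$beta_ratio), max(x$beta_ratio)))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, ...) {
  graphics::plot(x$time, x$beta_ratio, xlab = "time (min)",
                 ylab = "I(538)/I(505)", main = x$label, ...)
  if (!is.null(x$sem))
    graphics::arrows(x$time, x$beta_ratio - x$sem, x$time,
                     x$beta_ratio + x$sem, angle = 90, code = 3,
                     length = 0.02)
  invisible(x)
}

#' Assemble a kinetic trace from replicated spectra
#'
#' Computes the [beta_ratio()] of every spectrum, groups by `time_label`
#' and returns per-time mean and standard error across replicates. Every
#' replicate series must cover the same set of time points.
#'
#' @param spectra List of [absorbance_spectrum()] objects, each carrying a
#'   `time_label`.
#' @param bound_nm,free_nm Passed to [beta_ratio()].
#' @param label Condition label for the trace.
#' @return A [kinetic_trace()]; `sem` is `NULL` when every time point has
#'   a single replicate.
#' @export
build_kinetic_trace <- function(spectra, bound_nm = 538, free_nm = 505,
                                label = "") {
  if (!length(spectra)) stop("'spectra' is empty")
  tl <- lapply(spectra, `[[`, "time_label")
  if (any(vapply(tl, is.null, logical(1L))))
    stop("every spectrum needs a 'time_label' to build a kinetic trace")
  times <- vapply(spectra, `[[`, numeric(1L), "time_label")
  ratios <- vapply(spectra, function(s)
    as.numeric(beta_ratio(s, bound_nm, free_nm)), numeric(1L))
  counts <- table(times)
  if (length(unique(as.integer(counts))) != 1L)
    stop("replicate series do not share time labels: counts per time are ",
         paste(sprintf("t=%s:%d", names(counts), as.integer(counts)),
               collapse = ", "))
  tt <- sort(unique(times))
  mean_r <- vapply(tt, function(t0) mean(ratios[times == t0]), numeric(1L))
  nrep <- as.integer(counts[1L])
  sem <- if (nrep > 1L)
    vapply(tt, function(t0) stats::sd(ratios[times == t0]) / sqrt(nrep),
           numeric(1L))
  else NULL
  kinetic_trace(tt, mean_r, sem = sem, n_replicates = nrep, label = label)
}

#' Read/write spectra and kinetic traces as CSV
#'
#' `read_spectra_csv` expects columns `wavelength_nm`, `absorbance` and
#' optionally `time_min` and `replicate`; one spectrum is returned per
#' (time, replicate) combination. `write_kinetic_trace_csv` /
#' `read_kinetic_trace_csv` use columns `time_min`, `ratio`, `sem`.
#'
#' @param path CSV path.
#' @return `read_spectra_csv`: list of [absorbance_spectrum()];
#'   `read_kinetic_trace_csv`: a [kinetic_trace()].
#' @export
read_spectra_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "absorbance") %in% names(d)))
    stop("expected columns wavelength_nm, absorbance in ", path)
  if (is.null(d$time_min)) d$time_min <- NA_real_
  if (is.null(d$replicate)) d$replicate <- 1L
  split_by <- interaction(d$time_min, d$replicate, drop = TRUE)
  out <- lapply(split(d, split_by), function(g) {
    g <- g[order(g$wavelength_nm), ]
    absorbance_spectrum(g$wavelength_nm, g$absorbance,
                        time_label = if (all(is.na(g$time_min))) NULL
                                     else g$time_min[1L],
                        replicate = g$replicate[1L])
  })
  names(out) <- NULL
  out
}

#' @rdname read_spectra_csv
#' @param trace A [kinetic_trace()].
#' @export
write_kinetic_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  d <- data.frame(time_min = trace$time, ratio = trace$beta_ratio,
                  sem = if (is.null(trace$sem)) NA_real_ else trace$sem)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_spectra_csv
#' @export
read_kinetic_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_min", "ratio") %in% names(d)))
    stop("expected columns time_min, ratio in ", path)
  sem <- if (!is.null(d$sem) && !all(is.na(d$sem))) d$sem else NULL
  kinetic_trace(d$time_min, d$ratio, sem = sem,
                label = basename(path))
}
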