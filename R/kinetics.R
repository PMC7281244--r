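# Sigmoidal fibrillation kinetics: 4-parameter logistic fits of beta-ratio
# time courses, with the tangent-intercept lag-time convention standard in
# amyloid kinetics, and comparison of solvent conditions.

logistic4 <- function(t, baseline, plateau, t_half, rate) {
  baseline + (plateau - baseline) / (1 + exp(-rate * (t - t_half)))
}

#' Fit a 4-parameter logistic to a fibrillation time course
#'
#' Weighted (by `1/sem^2` when standard errors are present) least-squares
#' fit of \eqn{y(t) = y_0 + (y_\infty - y_0) / (1 + e^{-k(t - t_{1/2})})}.
#' The lag time uses the tangent-intercept convention
#' \eqn{t_{lag} = t_{1/2} - 2/k}, floored at zero. The fit is flagged
#' `censored` when the trace has not (yet) reached its plateau: either the
#' last observed value is below 90% of the fitted plateau, or the fitted
#' midpoint lies beyond the last time point, or the trace is flat to
#' within 5% of its scale (a "blocked" condition).
#'
#' @param trace A [kinetic_trace()] with at least 6 time points.
#' @return An object of class `"sigmoid_fit"`: `baseline`, `plateau`,
#'   `t_half` (min), `rate` (1/min), `lag_time` (min), `residual_rms`,
#'   `censored` (logical) and the source trace. Methods: `print`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @examples
#' t <- seq(0, 240, by = 20)
#' tr <- kinetic_trace(t, logistic4(t, 0.3, 1.2, 100, 0.08))
#' fit_sigmoid(tr)
#' @export
fit_sigmoid <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time
  y <- trace$beta_ratio
  if (length(t) < 6L)
    stop("fit_sigmoid needs at least 6 time points")
  w <- if (!is.null(trace$sem) && all(trace$sem > 0)) 1 / trace$sem^2
       else rep(1, length(t))
  scale_y <- max(abs(y), .Machine$double.eps)
  flat <- (max(y) - min(y)) < 0.05 * scale_y
  if (flat) {
    # a flat trace carries no kinetic information: report the level and
    # flag it censored rather than fitting an unidentifiable sigmoid
    m <- stats::weighted.mean(y, w)
    return(structure(
      list(baseline = m, plateau = m, t_half = NA_real_, rate = NA_real_,
           lag_time = NA_real_, residual_rms = sqrt(mean((y - m)^2)),
           censored = TRUE, flat = TRUE, trace = trace,
           model = "4-parameter logistic, tangent-intercept lag"),
      class = "sigmoid_fit"))
  }
  # inits: baseline/plateau from the trace ends, midpoint from the
  # half-rise crossing, rate from the steepest observed slope
  b0 <- min(y)
  p0 <- max(y)
  half <- b0 + (p0 - b0) / 2
  i_half <- which(y >= half)[1L]
  t0 <- if (is.na(i_half) || i_half == 1L) stats::median(t) else t[i_half]
  slopes <- diff(y) / pmax(diff(t), .Machine$double.eps)
  k0 <- max(4 * max(slopes) / (p0 - b0), 1e-3)
  span <- max(t) - min(t)
  par0 <- c(baseline = b0, delta = p0 - b0, t_half = t0, rate = k0)
  lower <- c(0, 0, min(t) - span, 1e-5)
  upper <- c(2 * p0, 4 * p0, max(t) + 2 * span, 10)
  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper,
    fn = function(p) sqrt(w) *
      (y - logistic4(t, p[1L], p[1L] + p[2L], p[3L], p[4L])),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  if (!(fit$info %in% 1:4))
    stop("logistic fit did not converge: ", fit$message)
  p <- fit$par
  baseline <- p[["baseline"]]
  plateau <- baseline + p[["delta"]]
  t_half <- p[["t_half"]]
  rate <- p[["rate"]]
  yhat <- logistic4(t, baseline, plateau, t_half, rate)
  censored <- y[length(y)] < 0.9 * plateau || t_half > max(t)
  structure(
    list(baseline = baseline, plateau = plateau, t_half = t_half,
         rate = rate, lag_time = max(0, t_half - 2 / rate),
         residual_rms = sqrt(mean((y - yhat)^2)),
         censored = censored, flat = FALSE, trace = trace,
         model = "4-parameter logistic, tangent-intercept lag"),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Fibrillation kinetics fit (", x$model, ")\n", sep = "")
  if (x$flat) {
    cat(sprintf("  flat trace at ratio %.3g - censored (no kinetics)\n",
                x$baseline))
    return(invisible(x))
  }
  cat(sprintf("  baseline %.3g, plateau %.3g, t1/2 = %.4g min, rate = %.4g /min\n",
              x$baseline, x$plateau, x$t_half, x$rate))
  cat(sprintf("  lag time = %.4g min, residual RMS = %.3g%s\n",
              x$lag_time, x$residual_rms,
              if (x$censored) "  [censored: plateau not reached]" else ""))
  invisible(x)
}

#' @export
coef.sigmoid_fit <- function(object, ...) {
  c(baseline = object$baseline, plateau = object$plateau,
    t_half = object$t_half, rate = object$rate,
    lag_time = object$lag_time)
}

#' @export
predict.sigmoid_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) time <- object$trace$time
  if (object$flat) return(rep(object$baseline, length(time)))
  logistic4(time, object$baseline, object$plateau, object$t_half,
            object$rate)
}

#' @export
residuals.sigmoid_fit <- function(object, ...) {
  object$trace$beta_ratio - predict(object)
}

#' @export
plot.sigmoid_fit <- function(x, ...) {
  plot(x$trace, ...)
  tt <- seq(min(x$trace$time), max(x$trace$time), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = 2, lwd = 2)
  invisible(x)
}

#' Compare fibrillation kinetics across conditions
#'
#' Tabulates lag, rate and plateau for a set of fitted conditions and
#' reports pairwise differences from a reference condition with seeded
#' residual-resampling bootstrap confidence intervals. A condition is
#' labelled `"blocked"` when it never develops meaningful signal: censored
#' (or showing less than 5% of the reference signal rise) while sitting
#' below `blocked_fraction` of the reference plateau - the signature of a
#' condition (e.g. lysozyme + trehalose without salt) where fibrillation
#' never starts.
#'
#' @param fits Named list of `"sigmoid_fit"` objects (at least 2).
#' @param reference Name or index of the reference condition (default 1).
#' @param n_boot Bootstrap replicates per condition (default 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param blocked_fraction Fraction of the reference plateau below which a
#'   censored condition counts as blocked (default 0.2).
#' @return A data frame of class `"kinetics_comparison"`: one row per
#'   condition with `lag`, `rate`, `plateau`, `censored`, `blocked`,
#'   differences from the reference (`d_lag`, `d_rate`, `d_plateau`) and
#'   bootstrap CI bounds for the differences.
#' @export
compare_conditions <- function(fits, reference = 1L, n_boot = 100L,
                               seed = 1L, level = 0.95,
                               blocked_fraction = 0.2) {
  if (length(fits) < 2L) stop("compare_conditions needs at least two fits")
  stopifnot(all(vapply(fits, inherits, logical(1L), what = "sigmoid_fit")))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("condition", seq_along(fits))
  ref_i <- if (is.character(reference)) match(reference, nm)
           else as.integer(reference)
  if (is.na(ref_i) || ref_i < 1L || ref_i > length(fits))
    stop("unknown reference condition")
  ref <- fits[[ref_i]]
  boot_params <- function(fit, seed_i) {
    if (fit$flat)
      return(matrix(rep(c(NA, NA, fit$baseline), each = n_boot), ncol = 3,
                    dimnames = list(NULL, c("lag", "rate", "plateau"))))
    set.seed(seed_i)
    res <- residuals(fit)
    yhat <- predict(fit)
    out <- matrix(NA_real_, n_boot, 3,
                  dimnames = list(NULL, c("lag", "rate", "plateau")))
    for (b in seq_len(n_boot)) {
      yb <- pmax(0, yhat + sample(res, replace = TRUE))
      fb <- tryCatch(
        fit_sigmoid(kinetic_trace(fit$trace$time, yb, sem = fit$trace$sem)),
        error = function(e) NULL)
      if (!is.null(fb) && !fb$flat)
        out[b, ] <- c(fb$lag_time, fb$rate, fb$plateau)
    }
    out
  }
  boots <- lapply(seq_along(fits), function(i)
    boot_params(fits[[i]], seed + i))
  alpha <- (1 - level) / 2
  ref_rise <- ref$plateau - ref$baseline
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    level_now <- if (f$flat) f$baseline else f$plateau
    rise <- level_now - f$baseline
    # blocked = the condition never develops meaningful signal: censored
    # (or essentially no rise relative to the reference) at a level far
    # below the reference plateau
    blocked <- (f$censored || rise < 0.05 * ref_rise) &&
      level_now < blocked_fraction * ref$plateau
    d <- boots[[i]] - boots[[ref_i]]
    ci <- function(col) {
      if (i == ref_i) return(c(0, 0))
      v <- d[, col]
      if (all(is.na(v))) return(c(NA_real_, NA_real_))
      stats::quantile(v, c(alpha, 1 - alpha), na.rm = TRUE)
    }
    cl <- ci("lag"); cr <- ci("rate"); cp <- ci("plateau")
    data.frame(condition = nm[i],
               lag = f$lag_time, rate = f$rate, plateau = level_now,
               censored = f$censored, blocked = blocked,
               d_lag = f$lag_time - ref$lag_time,
               d_lag_lo = cl[1L], d_lag_hi = cl[2L],
               d_rate = f$rate - ref$rate,
               d_plateau = level_now - ref$plateau,
               d_plateau_lo = cp[1L], d_plateau_hi = cp[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- nm[ref_i]
  class(out) <- c("kinetics_comparison", "data.frame")
  out
}

#' @export
print.kinetics_comparison <- function(x, ...) {
  ref <- attr(x, "reference")
  cat("Kinetics comparison (reference: ",
      if (is.null(ref)) "<unset>" else ref, ")\n", sep = "")
  cols <- intersect(c("condition", "lag", "rate", "plateau", "censored",
                      "blocked", "d_lag", "d_plateau"), names(x))
  print.data.frame(as.data.frame(x)[, cols], digits = 4)
  invisible(x)
}
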