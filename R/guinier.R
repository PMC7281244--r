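# Model-free size analysis: classical Guinier for globular particles,
# cross-sectional (rod-like) Guinier for elongated particles, sequential
# two-population rod decomposition, and Kratky shape classification.

# Shared linearized-Guinier engine.
#
# kind "globular": ln I       = ln I(0) - Q^2 Rg^2 / 3,  window Q*Rg <= rule
# kind "rod":      ln (Q I)   = ln I(0) - Q^2 Rc^2 / 2,  window Q*Rc <= rule
#
# The window is found iteratively: fit, convert the slope to a size, keep the
# points with Q*size <= rule, refit, until the point set is stable. If the
# iteration oscillates between windows the wider window wins. After
# convergence, leading low-Q points that fall systematically below the line
# (most negative residual, beyond 1.5 x RMS) are trimmed: for rods this is
# the region Q*L ~ 1 where the 1/Q regime is not yet reached, for globular
# samples incipient aggregation. Weighted regression uses the propagated
# log-space uncertainty sigma/I when sigma is present.
guinier_engine <- function(curve, kind = c("globular", "rod"),
                           qmax_rule = NULL, min_points = 5L,
                           subset = NULL, enforce_rule = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "saxs_curve"))
  rule <- if (is.null(qmax_rule)) c(globular = 1.3, rod = 1.0)[[kind]]
          else qmax_rule
  keep <- if (is.null(subset)) seq_along(curve$q) else subset
  q <- curve$q[keep]
  i <- curve$intensity[keep]
  s <- if (is.null(curve$sigma)) NULL else curve$sigma[keep]
  pos <- i > 0
  q <- q[pos]; i <- i[pos]; if (!is.null(s)) s <- s[pos]
  if (length(q) < min_points)
    stop("no Guinier regime: fewer than ", min_points,
         " positive-intensity points")
  x <- q^2
  y <- if (kind == "globular") log(i) else log(q * i)
  w <- if (is.null(s)) rep(1, length(q)) else (i / s)^2
  slope_to_size <- function(sl) {
    fac <- if (kind == "globular") 3 else 2
    if (!is.finite(sl) || sl >= 0) return(NA_real_)
    sqrt(-fac * sl)
  }
  do_fit <- function(sel) stats::lm.wfit(cbind(1, x[sel]), y[sel], w[sel])
  fit_size <- function(sel) slope_to_size(do_fit(sel)$coefficients[2L])
  # initial size estimate from the full window, halving it while the slope
  # is non-negative (e.g. a rising high-Q portion dominates)
  sel <- seq_along(q)
  size <- fit_size(sel)
  while (is.na(size) && length(sel) >= 2L * min_points) {
    sel <- sel[seq_len(ceiling(length(sel) / 2))]
    size <- fit_size(sel)
  }
  if (is.na(size))
    stop("no Guinier regime: non-negative slope of the linearized fit ",
         "(the sample does not show ", kind, " Guinier behaviour)")
  # damped fixed-point iteration on the size; the window follows Q*size<=rule
  window_of <- function(size) {
    sel <- which(q <= rule / size)
    if (length(sel) < min_points) sel <- seq_len(min_points)
    sel
  }
  prev_sel <- integer(0)
  converged <- FALSE
  for (iter in 1:200) {
    sel <- window_of(size)
    if (identical(sel, prev_sel)) { converged <- TRUE; break }
    new_size <- fit_size(sel)
    if (is.na(new_size))
      stop("no Guinier regime: non-negative slope inside the ",
           "rule-selected window")
    prev_sel <- sel
    size <- sqrt(size * new_size)  # damping avoids window oscillation
  }
  if (!converged)
    stop("no Guinier regime: iterative range selection did not converge")
  size <- fit_size(sel)
  if (is.na(size))
    stop("no Guinier regime: non-negative slope at convergence")
  # converged window must actually respect the validity rule (a forced
  # minimal window that still violates it means there is no linear regime);
  # rough bootstrap estimates may waive this
  if (enforce_rule && q[sel[length(sel)]] * size > rule * 1.05)
    stop(sprintf(paste0("no Guinier regime: smallest usable window violates ",
                        "Q*size <= %.3g (Q*size = %.3g)"),
                 rule, q[sel[length(sel)]] * size))
  # Trim low-Q points that droop systematically below the line (rods not yet
  # in their 1/Q regime, subtraction artifacts). The droop must be one-sided:
  # markedly deeper than any negative residual at the high-Q end, so that the
  # symmetric concave curvature of a globular curve does not trigger it.
  repeat {
    f <- do_fit(sel)
    r <- f$residuals
    rmse <- sqrt(mean(r^2))
    if (length(sel) > min_points + 1L && rmse > 1e-12 &&
        r[1L] < -1.5 * rmse && r[1L] == min(r))
      sel <- sel[-1L]
    else break
  }
  f <- do_fit(sel)
  size <- slope_to_size(f$coefficients[2L])
  if (is.na(size)) stop("no Guinier regime: degenerate final window")
  yhat <- f$fitted.values
  ss_res <- sum(w[sel] * (y[sel] - yhat)^2)
  ss_tot <- sum(w[sel] * (y[sel] - stats::weighted.mean(y[sel], w[sel]))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  structure(
    list(kind = kind,
         size = unname(size),
         forward = unname(exp(f$coefficients[1L])),
         q_range = c(q[sel[1L]], q[sel[length(sel)]]),
         r_squared = r2,
         n_points = length(sel),
         qmax_rule = rule,
         weighted = !is.null(s),
         data = data.frame(q = q[sel], x = x[sel], y = y[sel],
                           fitted = yhat)),
    class = "guinier_fit"
  )
}

#' Classical Guinier fit
#'
#' Estimates the radius of gyration of globular particles from the low-Q
#' approximation \eqn{d\Sigma/d\Omega(Q) = d\Sigma/d\Omega(0)
#' \exp(-Q^2 R_g^2/3)} by weighted linear regression of \eqn{\ln I} on
#' \eqn{Q^2}, with the fit range chosen iteratively so that
#' \eqn{Q R_g \le} `qmax_rule` at convergence. A sample with no convergent
#' low-Q linear regime (e.g. a mature fibril suspension) raises a
#' "no Guinier regime" error - itself a diagnostic that the particles are
#' not globular.
#'
#' @param curve A [saxs_curve()].
#' @param qmax_rule Dimensionless limit on \eqn{Q R_g} (default 1.3).
#' @return A `"guinier_fit"` object with fields `kind` (`"globular"`),
#'   `size` (\eqn{R_g}, \eqn{\mathrm{\AA}}), `forward`
#'   (\eqn{d\Sigma/d\Omega(0)}, \eqn{cm^{-1}}), `q_range`, `r_squared` and
#'   `n_points`; it has `print()`, `coef()`, `predict()`, `plot()` and
#'   `residuals()` methods.
#' @examples
#' q <- seq(0.01, 0.2, length.out = 80)
#' crv <- saxs_curve(q, 7 * exp(-q^2 * 256 / 3))
#' guinier_fit(crv)  # Rg = 16, I(0) = 7
#' @export
guinier_fit <- function(curve, qmax_rule = 1.3) {
  guinier_engine(curve, "globular", qmax_rule)
}

#' Rod-like (cross-sectional) Guinier fit
#'
#' For long rod-shaped particles the low-Q intensity follows
#' \eqn{d\Sigma/d\Omega(Q) = \frac{1}{Q} d\Sigma/d\Omega(0)
#' \exp(-Q^2 R_c^2/2)}; this fits \eqn{\ln(Q I)} against \eqn{Q^2} with the
#' iterative window \eqn{Q R_c \le} `qmax_rule`. For a uniform circular
#' cross section of geometric radius R, \eqn{R_c = R/\sqrt{2}}.
#'
#' @inheritParams guinier_fit
#' @param qmax_rule Dimensionless limit on \eqn{Q R_c} (default 1.0).
#' @return A `"guinier_fit"` object with `kind = "rod"` and `size`
#'   \eqn{= R_c}.
#' @examples
#' q <- seq(0.005, 0.05, length.out = 60)
#' crv <- saxs_curve(q, (1 / q) * exp(-q^2 * 450))
#' rodlike_guinier_fit(crv)  # Rc = 30
#' @export
rodlike_guinier_fit <- function(curve, qmax_rule = 1.0) {
  guinier_engine(curve, "rod", qmax_rule)
}

#' @export
print.guinier_fit <- function(x, ...) {
  nm <- if (x$kind == "globular") "Rg" else "Rc"
  cat(sprintf("%s Guinier fit (%s)\n",
              if (x$kind == "globular") "Classical" else "Rod-like",
              if (x$weighted) "weighted" else "unweighted"))
  cat(sprintf("  %s = %.4g A, forward intensity = %.4g cm^-1\n",
              nm, x$size, x$forward))
  cat(sprintf("  window: Q in [%.4g, %.4g] A^-1 (%d points, Q*%s <= %.3g)\n",
              x$q_range[1L], x$q_range[2L], x$n_points, nm, x$qmax_rule))
  cat(sprintf("  R^2 = %.6f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) {
  stats::setNames(c(object$size, object$forward),
                  c(if (object$kind == "globular") "Rg" else "Rc",
                    "forward"))
}

#' @export
predict.guinier_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) q <- object$data$q
  if (object$kind == "globular")
    object$forward * exp(-q^2 * object$size^2 / 3)
  else
    object$forward / q * exp(-q^2 * object$size^2 / 2)
}

#' @export
residuals.guinier_fit <- function(object, ...) {
  object$data$y - object$data$fitted
}

#' @export
plot.guinier_fit <- function(x, ...) {
  ylab <- if (x$kind == "globular") expression(ln ~ I) else
    expression(ln ~ (Q %.% I))
  graphics::plot(x$data$x, x$data$y, xlab = expression(Q^2 ~ (ring(A)^-2)),
                 ylab = ylab, ...)
  graphics::lines(x$data$x, x$data$fitted, col = 2)
  invisible(x)
}

# Extrapolated model intensity of one rod-Guinier population
rod_population_model <- function(fit, q) {
  fit$forward / q * exp(-q^2 * fit$size^2 / 2)
}

# Weighted joint fit of two rod-Guinier populations on the union of their
# validity windows; seeded by two single-population fits. Windows follow
# the current size estimates and are updated over a few outer passes.
joint_two_rod_fit <- function(curve, fit1, fit2, qmax_rule,
                              q_lo = 0, n_outer = 3L,
                              include_large_high = FALSE) {
  q_all <- curve$q
  i_all <- curve$intensity
  pos <- i_all > 0 & q_all >= q_lo * 0.999
  q_all <- q_all[pos]
  i_all <- i_all[pos]
  w_all <- if (is.null(curve$sigma)) rep(1, sum(pos))
           else (i_all / curve$sigma[pos])^2
  rc1 <- max(fit1$size, fit2$size)
  rc2 <- min(fit1$size, fit2$size)
  a1 <- fit1$forward
  a2 <- fit2$forward
  if (rc1 / rc2 < 1.4) {
    # collapsed seed pair: a scale-dominant small population pulls the
    # initial single fit down onto the small size, and its forward then
    # approximates A1 + A2, not A1. Spread the pair so the windows exist;
    # the fit relocates the large size.
    rc1 <- 2.5 * rc2
    a1 <- max(fit1$forward - fit2$forward, 0.1 * fit1$forward)
  }
  # the size ordering is structural: rc1 = 1.4 * rc2 + d with d >= 0, so
  # the two components cannot swap roles during optimisation
  p <- c(lnA1 = log(a1), lnA2 = log(a2),
         d = max(rc1 - 1.4 * rc2, 1), rc2 = rc2)
  cur_rc <- function(p) c(rc1 = 1.4 * p[["rc2"]] + p[["d"]],
                          rc2 = p[["rc2"]])
  sel <- NULL
  t2 <- 2.5
  for (outer in seq_len(n_outer)) {
    rc <- cur_rc(p)
    # the high-Q band needs the large population decayed (threshold 2.5);
    # for size ratios near 2 that band would be empty, so the threshold
    # relaxes stepwise and the residual contamination (a few percent)
    # becomes part of the stated resolution limit
    t2 <- 2.5
    band2_n <- function(th) sum(q_all * rc[["rc1"]] >= th &
                                  q_all * rc[["rc2"]] <= 1.35 * qmax_rule)
    while (t2 > 2.0 && band2_n(t2) < 5L) t2 <- t2 - 0.25
    sel_new <- which(q_all * rc[["rc1"]] <= qmax_rule |
                       (q_all * rc[["rc1"]] >= t2 &
                          q_all * rc[["rc2"]] <= 1.35 * qmax_rule))
    if (length(sel_new) < 8L) return(NULL)
    if (identical(sel_new, sel) && outer > 1L) break
    sel <- sel_new
    qq <- q_all[sel]
    y <- log(qq * i_all[sel])
    sw <- sqrt(w_all[sel])
    # in the high-Q band the large population is past its Guinier regime
    # and its true contribution is below the percent level: modelling its
    # (much larger) Gaussian tail there would over-subtract, so the model
    # is piecewise - both populations at low Q, the small one alone at
    # high Q. When the current size estimates leave that band empty (e.g.
    # a collapsed initial pair), the full two-population model is fitted
    # on the low-Q window alone and the bands are recomputed from the
    # updated sizes on the next pass.
    high_band <- qq * rc[["rc1"]] >= t2
    # each population carries the higher-order terms of the uniform
    # circular cross section, ln(Q I) = ln A - Q^2 Rc^2/2 - Q^4 Rc^4/48
    # - Q^6 Rc^6/576 (the series of ln[2 J1(x)/x]^2 at x = Q Rc sqrt(2)):
    # without them the small population's window-edge droop biases its
    # size and spoils the extrapolation into the low-Q band
    rod_comp <- function(lnA, rcv)
      exp(lnA - qq^2 * rcv^2 / 2 - qq^4 * rcv^4 / 48 -
            qq^6 * rcv^6 / 576)
    # whether the large component also enters the high-Q band (through
    # its series tail) or is dropped there entirely is configuration
    # dependent; both variants are fitted and the better-scoring one wins
    comp1_mask <- if (include_large_high) rep(1, length(qq))
                  else as.numeric(!high_band)
    fit <- minpack.lm::nls.lm(
      par = p,
      lower = c(-60, -60, 0, 1), upper = c(60, 60, 2000, 1000),
      fn = function(pp) {
        m <- rod_comp(pp[2L], pp[4L]) +
          comp1_mask * rod_comp(pp[1L], 1.4 * pp[4L] + pp[3L])
        sw * (y - log(m))
      },
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!(fit$info %in% 1:4)) return(NULL)
    p <- stats::setNames(unlist(fit$par), names(p))
  }
  rc <- cur_rc(p)
  p <- c(p[c("lnA1", "lnA2")], rc1 = rc[["rc1"]], rc2 = rc[["rc2"]])
  qq <- q_all[sel]
  y <- log(qq * i_all[sel])
  rod_final <- function(lnA, rcv)
    exp(lnA - qq^2 * rcv^2 / 2 - qq^4 * rcv^4 / 48 - qq^6 * rcv^6 / 576)
  comp1_mask <- if (include_large_high) rep(1, length(qq))
                else as.numeric(!(qq * p[["rc1"]] >= t2))
  m <- comp1_mask * rod_final(p[["lnA1"]], p[["rc1"]]) +
    rod_final(p[["lnA2"]], p[["rc2"]])
  ww <- w_all[sel]
  r2 <- {
    ss_res <- sum(ww * (y - log(m))^2)
    ss_tot <- sum(ww * (y - stats::weighted.mean(y, ww))^2)
    if (ss_tot > 0) max(0, min(1, 1 - ss_res / ss_tot)) else 1
  }
  mk <- function(size, forward, win_sel) {
    structure(
      list(kind = "rod", size = size, forward = forward,
           q_range = range(q_all[win_sel]), r_squared = r2,
           n_points = length(win_sel), qmax_rule = qmax_rule,
           weighted = !is.null(curve$sigma),
           data = data.frame(q = qq, x = qq^2, y = y, fitted = log(m))),
      class = "guinier_fit")
  }
  win1 <- sel[q_all[sel] * p[["rc1"]] <= qmax_rule]
  win2 <- sel[q_all[sel] * p[["rc1"]] >= t2]
  if (length(win1) < 3L || length(win2) < 3L) return(NULL)
  list(large = mk(p[["rc1"]], exp(p[["lnA1"]]), win1),
       small = mk(p[["rc2"]], exp(p[["lnA2"]]), win2),
       score = sum(ww * (y - log(m))^2) / length(sel))
}

#' Two-population rod decomposition
#'
#' Sequential cross-sectional Guinier analysis for samples containing two
#' families of elongated particles (e.g. mature fibrils plus protofibrils):
#' the large-\eqn{R_c} population is fitted in its low-Q window, its
#' extrapolated \eqn{(1/Q)\exp(-Q^2R_c^2/2)} contribution subtracted, and
#' the small-\eqn{R_c} population fitted in the higher-Q window
#' (Q above the first window). Because each population contaminates the
#' other's window, the subtract-and-refit pass is alternated until both
#' radii are stable. Residuals below `mask_sigma` times the local
#' uncertainty are masked before the second fit.
#'
#' @param curve A [saxs_curve()].
#' @param qmax_rule Dimensionless window limit on \eqn{Q R_c} for both fits.
#' @param mask_sigma Residual masking threshold (in units of sigma) for the
#'   second population; used only when the curve carries uncertainties.
#' @param max_passes Maximum alternating refinement passes.
#' @return A list of class `"two_population_rod_fit"` with elements
#'   `large` and `small` (each a `"guinier_fit"`, larger \eqn{R_c} first
#'   regardless of detection order) and `small_detected` (logical; `FALSE`
#'   when the residual after removing the first population supports no
#'   second rod regime, in which case `small` is `NULL`).
#' @examples
#' q <- seq(0.002, 0.06, length.out = 200)
#' mix <- species_mixture(cylinder_species(108.9, 4000, scale = 1),
#'                        cylinder_species(42.4, 4000, scale = 1))
#' two_population_rod_fit(mixture_intensity(q, mix))
#' @export
two_population_rod_fit <- function(curve, qmax_rule = 1.0, mask_sigma = 3,
                                   max_passes = 25L) {
  stopifnot(inherits(curve, "saxs_curve"))
  q <- curve$q
  i <- curve$intensity
  fit1 <- guinier_engine(curve, "rod", qmax_rule)
  fit2 <- NULL
  make_sub <- function(intensity, floor_sigma = NULL, qmin = 0,
                       past_peak = FALSE) {
    keep <- which(q > qmin & intensity > 0)
    if (!is.null(curve$sigma) && !is.null(floor_sigma))
      keep <- keep[intensity[keep] > floor_sigma * curve$sigma[keep]]
    if (past_peak && length(keep) > 5L) {
      # a rod population has monotonically decreasing Q*I(Q); a rising
      # leading stretch is the subtraction artifact of the other
      # population's window and is excluded
      qi <- q[keep] * intensity[keep]
      keep <- keep[which.max(qi):length(keep)]
    }
    if (length(keep) < 5L) return(NULL)
    saxs_curve(q[keep], intensity[keep],
               sigma = if (is.null(curve$sigma)) NULL else curve$sigma[keep],
               label = curve$label)
  }
  # second-population fit on a residual curve: plain window first, and if
  # that shows no rod regime, retry past the peak of Q*I (a rising leading
  # stretch is the subtraction artifact of the first window)
  try_fit2 <- function(res2, qmin) {
    for (pp in c(FALSE, TRUE)) {
      sub2 <- make_sub(res2, floor_sigma = mask_sigma, qmin = qmin,
                       past_peak = pp)
      if (is.null(sub2)) next
      # the past-peak retry is a rescue estimate refined by later passes,
      # so it does not have to satisfy the strict window rule
      f <- tryCatch(guinier_engine(sub2, "rod", qmax_rule,
                                   enforce_rule = !pp),
                    error = function(e) NULL)
      if (!is.null(f)) return(f)
    }
    NULL
  }
  # Asymmetric sequential analysis. The small population is fitted on the
  # ORIGINAL curve in the higher-Q window beyond the large population's
  # decay (Q * Rc_large >= 2.2, where a rod's true contribution has fallen
  # to a few percent); subtracting a Gaussian extrapolation of the large
  # population there would over-subtract, because the true cross-section
  # form factor decays much faster than its Guinier Gaussian. The large
  # population is then refitted at low Q after subtracting the small
  # population's extrapolation - which IS reliable backwards, since
  # Q * Rc_small < 0.5 there. The pair of fits is alternated to
  # convergence. The initial single fit is a scale-weighted average of
  # both families, so the first small-population window is provisional.
  fit2_window <- function(rc_large) {
    idx <- which(q >= 2.2 / rc_large)
    if (length(idx) < 5L) return(NULL)
    tryCatch(guinier_engine(curve, "rod", qmax_rule * 1.2, subset = idx,
                            enforce_rule = FALSE),
             error = function(e) NULL)
  }
  fit2 <- fit2_window(fit1$size)
  if (is.null(fit2))
    fit2 <- try_fit2(i - rod_population_model(fit1, q), fit1$q_range[2L])
  if (!is.null(fit2)) {
    for (pass in seq_len(max_passes)) {
      res1 <- i - rod_population_model(fit2, q)
      sub1 <- make_sub(res1)
      fit1_new <- if (is.null(sub1)) NULL else
        tryCatch(guinier_engine(sub1, "rod", qmax_rule),
                 error = function(e) NULL)
      if (is.null(fit1_new)) break
      fit2_new <- fit2_window(fit1_new$size)
      if (is.null(fit2_new))
        fit2_new <- try_fit2(i - rod_population_model(fit1_new, q),
                             fit1_new$q_range[2L])
      if (is.null(fit2_new)) { fit1 <- fit1_new; break }
      done <- abs(fit1_new$size - fit1$size) < 1e-4 * fit1$size &&
        abs(fit2_new$size - fit2$size) < 1e-4 * fit2$size
      fit1 <- fit1_new
      fit2 <- fit2_new
      if (done) break
    }
  }
  # Joint refinement: a weighted fit of
  # ln(Q I) = ln(A1 e^{-Q^2 Rc1^2/2} + A2 e^{-Q^2 Rc2^2/2}) over the union
  # of the two validity windows (Q Rc1 <= rule, and Q Rc1 >= 2.5 with
  # Q Rc2 <= 1.35 rule - the band in between holds the large population
  # beyond its Guinier regime and is excluded). This removes the mutual
  # window contamination that limits pure subtraction at Rc ratios near 2.
  # Seeded from the sequential pair plus tail-anchored candidates: the
  # uppermost third of the grid determines the small size nearly
  # unmixed, and the large size is scanned over plausible multiples.
  tail_fit <- {
    n_all <- length(q)
    idx <- seq.int(ceiling(2 * n_all / 3), n_all)
    if (length(idx) >= 5L)
      tryCatch(guinier_engine(curve, "rod", qmax_rule, subset = idx,
                              enforce_rule = FALSE),
               error = function(e) NULL)
    else NULL
  }
  seeds <- list()
  if (!is.null(fit2)) seeds <- list(list(f1 = fit1, f2 = fit2))
  if (!is.null(tail_fit)) {
    a1_guess <- max(fit1$forward - tail_fit$forward, 0.05 * fit1$forward)
    for (f in c(1.6, 2.2, 3.0))
      seeds[[length(seeds) + 1L]] <-
        list(f1 = list(size = f * tail_fit$size, forward = a1_guess),
             f2 = tail_fit)
  }
  if (length(seeds)) {
    cands <- list()
    for (s in seeds) for (ilh in c(FALSE, TRUE))
      cands[[length(cands) + 1L]] <- tryCatch(
        joint_two_rod_fit(curve, s$f1, s$f2, qmax_rule,
                          q_lo = fit1$q_range[1L],
                          include_large_high = ilh),
        error = function(e) NULL)
    cands <- Filter(function(cc) !is.null(cc) && is.finite(cc$score),
                    cands)
    if (length(cands)) {
      best <- cands[[which.min(vapply(cands, `[[`, numeric(1L), "score"))]]
      fit1 <- best$large
      fit2 <- best$small
    }
  }
  # two genuinely distinct families, or a single population after all?
  # distinct means well-separated sizes AND both carrying real intensity
  if (!is.null(fit2)) {
    ratio <- max(fit1$size, fit2$size) / min(fit1$size, fit2$size)
    amp_ratio <- min(fit1$forward, fit2$forward) /
      max(fit1$forward, fit2$forward)
    if (!is.finite(ratio) || ratio < 1.4 ||
        !is.finite(amp_ratio) || amp_ratio < 0.01) {
      fit2 <- NULL
      fit1 <- guinier_engine(curve, "rod", qmax_rule)
    }
  }
  if (!is.null(fit2)) {
    # second population must occupy its own window; a second fit landing on
    # (or inside) the first window is an ambiguous decomposition
    if (fit2$q_range[1L] < fit1$q_range[1L])
      stop(sprintf(paste0("ambiguous two-population decomposition: windows ",
                          "overlap ([%.4g, %.4g] vs [%.4g, %.4g] A^-1)"),
                   fit1$q_range[1L], fit1$q_range[2L],
                   fit2$q_range[1L], fit2$q_range[2L]))
    if (fit2$size > fit1$size) { tmp <- fit1; fit1 <- fit2; fit2 <- tmp }
  }
  structure(list(large = fit1, small = fit2,
                 small_detected = !is.null(fit2)),
            class = "two_population_rod_fit")
}

#' @export
print.two_population_rod_fit <- function(x, ...) {
  cat("Two-population rod-like Guinier decomposition\n")
  cat(sprintf("  large population: Rc = %.4g A (window [%.4g, %.4g])\n",
              x$large$size, x$large$q_range[1L], x$large$q_range[2L]))
  if (x$small_detected)
    cat(sprintf("  small population: Rc = %.4g A (window [%.4g, %.4g])\n",
                x$small$size, x$small$q_range[1L], x$small$q_range[2L]))
  else cat("  small population: not detected\n")
  invisible(x)
}

#' Kratky shape classification
#'
#' Classifies a scattering curve from the shape of its Kratky transform
#' \eqn{Q^2 I(Q)}: compact globular particles give a bell-shaped peak whose
#' high-Q tail falls well below the maximum, flexible chains plateau, and
#' curves still rising at the end of the measured range (e.g. flat
#' intensity) are labelled `"rising"`.
#'
#' @param curve A [saxs_curve()] with at least 20 points, all intensities
#'   positive.
#' @param bell_fraction Tail/maximum ratio below which the curve counts as
#'   bell-shaped (default 0.5).
#' @param plateau_tol Relative half-width around the tail mean within which
#'   the tail counts as flat (default 0.15).
#' @param tail_fraction Fraction of the highest-Q points treated as the
#'   tail (default 0.2).
#' @return A list with `label` (`"bell"`, `"plateau"` or `"rising"`) and
#'   `score` \eqn{= 1 -} tail mean / maximum, clipped to `[0, 1]` (1 for a
#'   sharply peaked, fully decayed bell; about 0 for a plateau; 0 for a
#'   rising tail).
#' @examples
#' q <- seq(0.01, 0.45, length.out = 100)
#' kratky_shape_score(saxs_curve(q, sphere_form_factor(q, 20)))
#' @export
kratky_shape_score <- function(curve, bell_fraction = 0.5,
                               plateau_tol = 0.15, tail_fraction = 0.2) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (length(curve$q) < 20L)
    stop("kratky_shape_score needs at least 20 points")
  if (any(curve$intensity <= 0))
    stop("kratky_shape_score requires strictly positive intensities")
  k <- kratky_transform(curve)
  y <- k$q2i
  n <- length(y)
  n_tail <- max(5L, round(tail_fraction * n))
  tail <- y[(n - n_tail + 1L):n]
  tail_mean <- mean(tail)
  m <- max(y)
  i_max <- which.max(y)
  score <- min(1, max(0, 1 - tail_mean / m))
  label <- if (i_max < n - n_tail && tail_mean < bell_fraction * m) {
    "bell"
  } else if (max(abs(tail - tail_mean)) <= plateau_tol * abs(tail_mean)) {
    "plateau"
  } else {
    "rising"
  }
  if (label == "rising") score <- 0
  list(label = label, score = score, maximum = m, tail_mean = tail_mean,
       q_at_maximum = k$q[i_max])
}
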