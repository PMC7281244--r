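# Full-curve nonlinear least-squares fitting of a species mixture to a
# scattering curve: bounded Levenberg-Marquardt with seeded Latin-hypercube
# multi-start, curvature and bootstrap uncertainties, and AIC-style model
# ranking.

# Flat parameter addressing: "species<i>.<field>" or "background".
free_param_names <- function(mixture) {
  out <- "background"
  for (i in seq_along(mixture$species)) {
    s <- mixture$species[[i]]
    fields <- switch(species_type(s),
      cylinder = c("radius", "length", "polydispersity", "scale"),
      wormlike = c("contour_length", "kuhn_length", "cross_radius", "scale"),
      sphere = c("radius", "scale"),
      atomic = c("shell_contrast", "shell_thickness", "scale"),
      stop("unsupported species type"))
    out <- c(out, paste0("species", i, ".", fields))
  }
  out
}

get_param <- function(mixture, name) {
  if (name == "background") return(mixture$background)
  m <- regmatches(name, regexec("^species([0-9]+)\\.(.+)$", name))[[1L]]
  if (length(m) != 3L) stop("unknown parameter: ", name)
  mixture$species[[as.integer(m[2L])]][[m[3L]]]
}

set_params <- function(mixture, p) {
  for (name in names(p)) {
    if (name == "background") {
      mixture$background <- p[[name]]
    } else {
      m <- regmatches(name, regexec("^species([0-9]+)\\.(.+)$", name))[[1L]]
      if (length(m) != 3L) stop("unknown parameter: ", name)
      mixture$species[[as.integer(m[2L])]][[m[3L]]] <- p[[name]]
    }
  }
  mixture
}

#' Specification of a mixture fit
#'
#' Bundles the model template (a [species_mixture()] whose current values
#' are the fixed values and defaults), the free parameters with bounds and
#' initial values, and the random seed used for multi-start initial points.
#' Parameters are addressed as `"species<i>.<field>"` (e.g.
#' `"species1.radius"`) or `"background"`.
#'
#' @param mixture A [species_mixture()] template.
#' @param free Named list; each element a list/vector with `init`, `lower`,
#'   `upper` (finite, with `lower <= init <= upper`). When `init` is
#'   missing, the template's current value is used.
#' @param seed Integer seed driving the multi-start initial points.
#' @return An object of class `"fit_spec"`.
#' @examples
#' mix <- species_mixture(cylinder_species(35, 2000, 0.25, scale = 1),
#'                        background = 1e-3)
#' fit_spec(mix, free = list(
#'   "species1.radius" = c(init = 35, lower = 10, upper = 90),
#'   "species1.scale"  = c(init = 1,  lower = 0,  upper = 10)))
#' @export
fit_spec <- function(mixture, free, seed = 1L) {
  stopifnot(inherits(mixture, "species_mixture"))
  if (length(free) == 0L) stop("'free' must name at least one parameter")
  known <- free_param_names(mixture)
  bad <- setdiff(names(free), known)
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  free <- lapply(stats::setNames(names(free), names(free)), function(nm) {
    f <- as.list(free[[nm]])
    if (is.null(f$init)) f$init <- get_param(mixture, nm)
    f <- lapply(f[c("init", "lower", "upper")], as.numeric)
    if (any(vapply(f, length, 1L) != 1L) || !all(is.finite(unlist(f))))
      stop("parameter '", nm, "' needs finite scalar init, lower, upper")
    if (f$lower > f$init || f$init > f$upper)
      stop("parameter '", nm, "' must satisfy lower <= init <= upper")
    f
  })
  structure(list(mixture = mixture, free = free, seed = as.integer(seed)),
            class = "fit_spec")
}

#' @export
print.fit_spec <- function(x, ...) {
  cat(sprintf("Mixture fit specification: %d species, %d free parameters\n",
              length(x$mixture$species), length(x$free)))
  for (nm in names(x$free))
    cat(sprintf("  %-24s init %.4g in [%.4g, %.4g]\n", nm,
                x$free[[nm]]$init, x$free[[nm]]$lower, x$free[[nm]]$upper))
  invisible(x)
}

spec_model_intensity <- function(spec, p, q) {
  mix <- set_params(spec$mixture, as.list(p))
  mixture_intensity(q, mix)$intensity
}

#' Fit a species mixture to a scattering curve
#'
#' Minimises \eqn{\sum_i [(I_i - I_{model}(Q_i))/\sigma_i]^2} over the free
#' parameters of `spec` with bound-constrained Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). Besides the user-supplied initial point,
#' `n_starts - 1` further starting points are drawn from a seeded Latin
#' hypercube over the parameter box; the best converged start wins.
#' Parameter uncertainties come from the inverse curvature (Gauss-Newton
#' Hessian) at the optimum, scaled by the reduced chi-square. Species
#' fractions are shares of the total forward intensity
#' \eqn{d\Sigma/d\Omega(0)} (excluding background).
#'
#' @param curve A [saxs_curve()]; when `sigma` is absent, unit weights are
#'   used.
#' @param spec A [fit_spec()].
#' @param n_starts Number of optimisation starts (default 8).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `"mixture_fit"`: `best_parameters` (data
#'   frame with `estimate` and `se`), `chi2_reduced`, `species_fractions`,
#'   `convergence` (status, iterations, per-start diagnostics), `pinned`
#'   (names of parameters at a bound, with a warning), `trace` (running
#'   best objective across accepted evaluations) and the fitted `mixture`.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `predict`, `residuals`,
#'   `plot`.
#' @examples
#' q <- seq(0.01, 0.25, length.out = 60)
#' mix <- species_mixture(cylinder_species(40, 300, scale = 2),
#'                        background = 0.001)
#' crv <- mixture_intensity(q, mix)
#' sp <- fit_spec(mix, free = list(
#'   "species1.radius" = c(init = 50, lower = 10, upper = 100),
#'   "species1.scale" = c(init = 1, lower = 0, upper = 10)), seed = 7)
#' fit <- fit_mixture(crv, sp, n_starts = 2)
#' coef(fit)
#' @export
fit_mixture <- function(curve, spec, n_starts = 8L, max_iter = 120L) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(spec, "fit_spec"))
  k <- length(spec$free)
  n <- length(curve$q)
  if (n < 3L * k)
    stop("need at least 3x more data points (", n,
         ") than free parameters (", k, ")")
  par0 <- vapply(spec$free, `[[`, numeric(1L), "init")
  lower <- vapply(spec$free, `[[`, numeric(1L), "lower")
  upper <- vapply(spec$free, `[[`, numeric(1L), "upper")
  sig <- if (is.null(curve$sigma)) rep(1, n) else curve$sigma
  trace_env <- new.env(parent = emptyenv())
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  resid_fn <- function(p) {
    p <- stats::setNames(pmin(pmax(p, lower), upper), names(par0))
    r <- (curve$intensity - spec_model_intensity(spec, p, curve$q)) / sig
    ss <- sum(r^2)
    if (ss < trace_env$best) {
      trace_env$best <- ss
      trace_env$trace <- c(trace_env$trace, ss)
    }
    r
  }
  starts <- matrix(par0, nrow = 1L)
  if (n_starts > 1L) {
    set.seed(spec$seed)
    u <- lhs::randomLHS(n_starts - 1L, k)
    starts <- rbind(starts,
                    sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+"))
  }
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      minpack.lm::nls.lm(
        par = stats::setNames(starts[i, ], names(par0)),
        lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)),
      error = function(e) e)
  }
  ok <- vapply(runs, function(r)
    inherits(r, "nls.lm") && r$info %in% 1:4, logical(1L))
  diag <- lapply(runs, function(r) {
    if (inherits(r, "nls.lm"))
      list(status = r$info, message = r$message, deviance = r$deviance,
           iterations = r$niter)
    else list(status = NA_integer_, message = conditionMessage(r),
              deviance = NA_real_, iterations = NA_integer_)
  })
  if (!any(ok)) {
    msg <- vapply(diag, function(d)
      sprintf("[status %s] %s", d$status, d$message), character(1L))
    stop("no optimisation start converged:\n  ",
         paste(msg, collapse = "\n  "))
  }
  devs <- vapply(runs, function(r)
    if (inherits(r, "nls.lm")) r$deviance else Inf, numeric(1L))
  devs[!ok] <- Inf
  best <- runs[[which.min(devs)]]
  p_hat <- stats::setNames(pmin(pmax(unlist(best$par), lower), upper),
                           names(par0))
  chi2 <- best$deviance
  dof <- max(1L, n - k)
  chi2_red <- chi2 / dof
  # curvature (Gauss-Newton) covariance, scaled by reduced chi-square
  vc <- tryCatch({
    h <- best$hessian        # approx 2 J'J
    v <- solve(h / 2) * chi2_red
    dimnames(v) <- list(names(par0), names(par0))
    v
  }, error = function(e) NULL)
  se <- if (is.null(vc)) rep(NA_real_, k) else sqrt(pmax(0, diag(vc)))
  tolb <- 1e-8 * pmax(upper - lower, 1)
  pinned <- names(par0)[p_hat <= lower + tolb | p_hat >= upper - tolb]
  if (length(pinned))
    warning("parameter(s) pinned at a bound: ",
            paste(pinned, collapse = ", "))
  fitted_mix <- set_params(spec$mixture, as.list(p_hat))
  scales <- vapply(fitted_mix$species, `[[`, numeric(1L), "scale")
  fractions <- if (sum(scales) > 0) scales / sum(scales)
               else rep(NA_real_, length(scales))
  structure(
    list(best_parameters = data.frame(estimate = p_hat, se = se,
                                      row.names = names(par0)),
         chi2 = chi2,
         chi2_reduced = chi2_red,
         species_fractions = fractions,
         convergence = list(status = best$info, message = best$message,
                            iterations = best$niter,
                            start_used = which.min(devs),
                            starts = diag),
         pinned = pinned,
         vcov = vc,
         trace = trace_env$trace,
         mixture = fitted_mix,
         spec = spec,
         curve = curve),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: %d species, chi2_red = %.4g (%s, %d iterations)\n",
              length(x$mixture$species), x$chi2_reduced,
              x$convergence$message, x$convergence$iterations))
  bp <- x$best_parameters
  for (i in seq_len(nrow(bp)))
    cat(sprintf("  %-24s %.5g +/- %.3g%s\n", rownames(bp)[i],
                bp$estimate[i], bp$se[i],
                if (rownames(bp)[i] %in% x$pinned) "  [at bound]" else ""))
  cat("  forward-intensity fractions:",
      paste(sprintf("%.1f%%", 100 * x$species_fractions), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.mixture_fit <- function(object, ...) {
  stats::setNames(object$best_parameters$estimate,
                  rownames(object$best_parameters))
}

#' @export
vcov.mixture_fit <- function(object, ...) object$vcov

#' @export
predict.mixture_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) q <- object$curve$q
  mixture_intensity(q, object$mixture, label = "fitted model")
}

#' @export
residuals.mixture_fit <- function(object, ...) {
  sig <- if (is.null(object$curve$sigma)) 1 else object$curve$sigma
  (object$curve$intensity -
     predict(object)$intensity) / sig
}

#' @export
summary.mixture_fit <- function(object, ...) {
  cat("Species mixture fit summary\n")
  print(object)
  cat(sprintf("  data: %d points, Q in [%.4g, %.4g] A^-1\n",
              length(object$curve$q), min(object$curve$q),
              max(object$curve$q)))
  if (!is.null(object$curve$sigma))
    cat("  weighted by experimental uncertainties\n")
  invisible(object)
}

#' @export
plot.mixture_fit <- function(x, ...) {
  plot(x$curve, ...)
  graphics::lines(x$curve$q, predict(x)$intensity, col = 2, lwd = 2)
  invisible(x)
}

#' Bootstrap parameter uncertainties
#'
#' Residual-resampling bootstrap around a converged [fit_mixture()] result:
#' the fitted model curve is perturbed by resampled (weighted) residuals,
#' refitted from the best-fit parameters, and the per-parameter empirical
#' standard deviation across replicates is returned. Deterministic given
#' `seed`.
#'
#' @param fit A `"mixture_fit"` object.
#' @param n_boot Number of bootstrap replicates (at least 20).
#' @param seed Integer seed.
#' @return Named numeric vector of empirical 1-sigma uncertainties; the
#'   matrix of replicate estimates is attached as attribute `"replicates"`.
#' @export
bootstrap_uncertainties <- function(fit, n_boot = 50L, seed = 1L) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (n_boot < 20L)
    stop("n_boot must be at least 20 for a usable empirical sigma")
  curve <- fit$curve
  model <- predict(fit)$intensity
  wres <- residuals(fit)          # (obs - model)/sigma
  sig <- if (is.null(curve$sigma)) rep(1, length(curve$q)) else curve$sigma
  p_hat <- coef(fit)
  spec_b <- fit$spec
  for (nm in names(spec_b$free)) spec_b$free[[nm]]$init <- unname(p_hat[nm])
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(p_hat),
                 dimnames = list(NULL, names(p_hat)))
  for (b in seq_len(n_boot)) {
    ib <- pmax(.Machine$double.xmin,
               model + sig * sample(wres, replace = TRUE))
    cb <- saxs_curve(curve$q, ib,
                     sigma = curve$sigma, label = curve$label)
    fb <- tryCatch(fit_mixture(cb, spec_b, n_starts = 1L),
                   error = function(e) NULL)
    if (!is.null(fb)) reps[b, ] <- coef(fb)
  }
  out <- apply(reps, 2L, stats::sd, na.rm = TRUE)
  attr(out, "replicates") <- reps
  out
}

#' Rank competing mixture models
#'
#' Fits every specification to the same curve and ranks them by total
#' chi-square plus an Akaike-style parsimony penalty of `2k` (k = number of
#' free parameters) on the chi-square scale. Specifications that fail to
#' converge are ranked after all successes, in input order, with their
#' error recorded.
#'
#' @param curve A [saxs_curve()].
#' @param specs List of at least two [fit_spec()] objects (optionally
#'   named).
#' @param n_starts Starts per fit (see [fit_mixture()]).
#' @return A data frame of class `"model_comparison"` with one row per
#'   model in rank order: `model`, `k`, `chi2`, `chi2_reduced`, `score`
#'   (\eqn{\chi^2 + 2k}), `status`; the fit objects are attached as
#'   attribute `"fits"` (in input order, `NULL` on failure).
#' @export
compare_models <- function(curve, specs, n_starts = 8L) {
  if (length(specs) < 2L) stop("compare_models needs at least two specs")
  nm <- names(specs)
  if (is.null(nm)) nm <- paste0("model", seq_along(specs))
  nm[!nzchar(nm)] <- paste0("model", which(!nzchar(nm)))
  fits <- vector("list", length(specs))
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    f <- tryCatch(fit_mixture(curve, specs[[i]], n_starts = n_starts),
                  error = function(e) e)
    k <- length(specs[[i]]$free)
    if (inherits(f, "mixture_fit")) {
      fits[[i]] <- f
      rows[[i]] <- data.frame(model = nm[i], k = k, chi2 = f$chi2,
                              chi2_reduced = f$chi2_reduced,
                              score = f$chi2 + 2 * k, status = "converged")
    } else {
      rows[[i]] <- data.frame(model = nm[i], k = k, chi2 = NA_real_,
                              chi2_reduced = NA_real_, score = Inf,
                              status = paste("failed:",
                                             conditionMessage(f)))
    }
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$score, seq_len(nrow(tab)))  # stable for ties
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (score = chi2 + 2k)\n")
  print.data.frame(x[, c("model", "k", "chi2_reduced", "score", "status")],
                   digits = 4)
  invisible(x)
}
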