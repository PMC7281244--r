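# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own quadrature paths: plain trapezoid integration at
# high resolution, closed forms, and direct evaluation.

# Brute-force orientation average of a monodisperse cylinder on a dense
# trapezoid grid (u = cos angle).
oracle_cylinder_P <- function(q, radius, length, n = 20001L) {
  u <- seq(0, 1, length.out = n)
  s <- sqrt(pmax(0, 1 - u^2))
  vapply(q, function(qq) {
    xr <- qq * radius * s
    amp_r <- ifelse(xr < 1e-8, 1, 2 * besselJ(pmax(xr, 1e-12), 1) / pmax(xr, 1e-12))
    xl <- qq * length * u / 2
    amp_l <- ifelse(xl < 1e-8, 1, sin(xl) / xl)
    pracma::trapz(u, (amp_r * amp_l)^2)
  }, numeric(1L))
}

# Brute-force double quadrature: orientation x truncated-Gaussian radius
# distribution with volume-squared (R^4) weighting, matching the stated
# population-averaging convention.
oracle_polydisperse_P <- function(q, radius, pd, length, n_r = 201L) {
  r <- seq(max(radius * 1e-6, radius * (1 - 3 * pd)), radius * (1 + 3 * pd),
           length.out = n_r)
  w <- stats::dnorm(r, radius, radius * pd) * r^4
  w <- w / sum(w)
  acc <- 0
  for (j in seq_along(r))
    acc <- acc + w[j] * oracle_cylinder_P(q, r[j], length, n = 4001L)
  acc
}

# Debye function of a Gaussian coil, I/I0 at x2 = (q Rg)^2
oracle_debye_coil <- function(q, rg) {
  x2 <- (q * rg)^2
  ifelse(x2 < 1e-8, 1, 2 * (exp(-x2) - 1 + x2) / x2^2)
}

# Smallest positive root of tan(x) = x (first zero of the sphere form
# factor amplitude), found by bisection on (pi, 3*pi/2).
oracle_sphere_first_zero <- function(tol = 1e-12) {
  f <- function(x) tan(x) - x
  lo <- pi + 1e-9
  hi <- 3 * pi / 2 - 1e-9
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Noise-free ratio trace of a scenario: the infinite-replicate limit the
# noisy kinetic simulations converge to.
noise_free_trace <- function(config) {
  f <- fibrillation_timecourse(config)
  ratios <- vapply(f, function(ff)
    as.numeric(beta_ratio(simulate_cr_spectrum(ff, noise = 0))),
    numeric(1L))
  kinetic_trace(config$time_grid, ratios)
}
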