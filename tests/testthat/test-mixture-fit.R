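test_that("fit_spec validates parameters and bounds", {
  mix <- species_mixture(sphere_species(20, scale = 1), background = 0.01)
  expect_error(fit_spec(mix, free = list(nope = c(init = 1, lower = 0,
                                                  upper = 2))),
               "unknown free parameter")
  expect_error(fit_spec(mix, free = list(
    "species1.radius" = c(init = 50, lower = 0, upper = 40))),
    "lower <= init <= upper")
  sp <- fit_spec(mix, free = list(
    "species1.radius" = c(init = 20, lower = 5, upper = 60)))
  expect_s3_class(sp, "fit_spec")
})

test_that("noise-free self-consistency recovers the generating parameters", {
  q <- seq(0.01, 0.3, length.out = 60)
  mix <- species_mixture(sphere_species(22, scale = 2),
                         background = 0.004)
  crv <- mixture_intensity(q, mix)
  sp <- fit_spec(mix, free = list(
    "species1.radius" = c(init = 22, lower = 5, upper = 60),
    "species1.scale" = c(init = 2, lower = 0, upper = 20),
    "background" = c(init = 0.004, lower = 0, upper = 1)), seed = 2)
  fit <- fit_mixture(crv, sp, n_starts = 1)
  expect_lt(max(abs(coef(fit) / c(22, 2, 0.004) - 1)), 1e-4)
  expect_lt(fit$chi2_reduced, 1e-10)
})

test_that("the accepted objective trace is monotone non-increasing", {
  q <- seq(0.01, 0.3, length.out = 60)
  mix <- species_mixture(sphere_species(22, scale = 2), background = 0.004)
  crv <- mixture_intensity(q, mix)
  set.seed(31)
  noisy <- saxs_curve(q, crv$intensity * (1 + rnorm(60, 0, 0.02)),
                      sigma = 0.02 * crv$intensity)
  sp <- fit_spec(mix, free = list(
    "species1.radius" = c(init = 35, lower = 5, upper = 60),
    "species1.scale" = c(init = 1, lower = 0, upper = 20)), seed = 4)
  fit <- fit_mixture(noisy, sp, n_starts = 2)
  expect_true(all(diff(fit$trace) <= 0))
  expect_gte(fit$chi2_reduced, 0)
})

test_that("species fractions sum to one and survive global rescaling", {
  q <- seq(0.008, 0.25, length.out = 70)
  mix <- species_mixture(wormlike_species(250, 50, 9.5, scale = 0.6),
                         wormlike_species(700, 60, 15.8, scale = 0.4),
                         background = 0.002)
  crv0 <- mixture_intensity(q, mix)
  set.seed(7)
  sig <- 0.01 * crv0$intensity
  ii <- crv0$intensity + rnorm(70, 0, sig)
  sp <- fit_spec(mix, free = list(
    "species1.scale" = c(init = 0.3, lower = 0, upper = 10),
    "species2.scale" = c(init = 0.3, lower = 0, upper = 10),
    "background" = c(init = 0.001, lower = 0, upper = 1)), seed = 11)
  f1 <- fit_mixture(saxs_curve(q, ii, sigma = sig), sp, n_starts = 1)
  expect_equal(sum(f1$species_fractions), 1, tolerance = 1e-9)
  # rescale data and sigma by the same constant: fractions unchanged
  c0 <- 37.5
  sp2 <- fit_spec(mix, free = list(
    "species1.scale" = c(init = 0.3, lower = 0, upper = 100),
    "species2.scale" = c(init = 0.3, lower = 0, upper = 100),
    "background" = c(init = 0.001, lower = 0, upper = 10)), seed = 11)
  f2 <- fit_mixture(saxs_curve(q, c0 * ii, sigma = c0 * sig), sp2,
                    n_starts = 1)
  expect_equal(f2$species_fractions, f1$species_fractions,
               tolerance = 1e-5)
})

test_that("fit refuses underdetermined problems and reports bound pinning", {
  q <- seq(0.01, 0.02, length.out = 5)
  mix <- species_mixture(sphere_species(20, scale = 1), background = 0)
  sp <- fit_spec(mix, free = list(
    "species1.radius" = c(init = 20, lower = 5, upper = 60),
    "species1.scale" = c(init = 1, lower = 0, upper = 5)), seed = 1)
  expect_error(fit_mixture(mixture_intensity(q, mix), sp), "3x more")

  qq <- seq(0.01, 0.3, length.out = 50)
  truth <- species_mixture(sphere_species(30, scale = 1), background = 0)
  sp_pin <- fit_spec(truth, free = list(
    "species1.radius" = c(init = 24, lower = 5, upper = 25),
    "species1.scale" = c(init = 1, lower = 0, upper = 5)), seed = 1)
  expect_warning(fit_mixture(mixture_intensity(qq, truth), sp_pin,
                             n_starts = 1),
                 "pinned")
})

test_that("bootstrap uncertainties: determinism, zero-noise collapse,
           curvature consistency", {
  q <- seq(0.01, 0.3, length.out = 60)
  mix <- species_mixture(sphere_species(22, scale = 2), background = 0)
  crv <- mixture_intensity(q, mix)
  sp <- fit_spec(mix, free = list(
    "species1.radius" = c(init = 22, lower = 5, upper = 60),
    "species1.scale" = c(init = 2, lower = 0, upper = 20)), seed = 2)
  fit0 <- fit_mixture(crv, sp, n_starts = 1)
  expect_error(bootstrap_uncertainties(fit0, n_boot = 5), "at least 20")
  b0 <- bootstrap_uncertainties(fit0, n_boot = 20, seed = 9)
  expect_true(all(b0 < 1e-6))
  # noisy fit: identical seeds agree; factor-2 agreement with curvature
  set.seed(5)
  sig <- 0.02 * crv$intensity
  noisy <- saxs_curve(q, crv$intensity + rnorm(60, 0, sig), sigma = sig)
  fitn <- fit_mixture(noisy, sp, n_starts = 1)
  b1 <- bootstrap_uncertainties(fitn, n_boot = 30, seed = 4)
  b2 <- bootstrap_uncertainties(fitn, n_boot = 30, seed = 4)
  expect_identical(b1, b2)
  curv <- fitn$best_parameters$se
  ratio <- as.numeric(b1) / curv
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("model comparison prefers the generating model", {
  q <- seq(0.008, 0.25, length.out = 70)
  truth <- species_mixture(wormlike_species(400, 40, 12, scale = 1),
                           background = 0.002)
  spec_true <- function() fit_spec(truth, free = list(
    "species1.cross_radius" = c(init = 8, lower = 1, upper = 40),
    "species1.scale" = c(init = 0.5, lower = 0, upper = 10),
    "background" = c(init = 0.001, lower = 0, upper = 1)), seed = 3)
  over <- species_mixture(wormlike_species(400, 40, 12, scale = 0.5),
                          wormlike_species(900, 70, 25, scale = 0.5),
                          background = 0.002)
  spec_over <- function() fit_spec(over, free = list(
    "species1.cross_radius" = c(init = 8, lower = 1, upper = 40),
    "species1.scale" = c(init = 0.5, lower = 0, upper = 10),
    "species2.cross_radius" = c(init = 20, lower = 1, upper = 60),
    "species2.scale" = c(init = 0.5, lower = 0, upper = 10),
    "background" = c(init = 0.001, lower = 0, upper = 1)), seed = 3)
  model0 <- mixture_intensity(q, truth)$intensity
  sig <- 0.02 * model0
  wins <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    crv <- saxs_curve(q, model0 + rnorm(70, 0, sig), sigma = sig)
    cmp <- compare_models(crv, list(true = spec_true(),
                                    over = spec_over()),
                          n_starts = 2)
    if (cmp$model[1L] == "true") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("identical specs tie with stable order; wrong family ranks last", {
  q <- seq(0.008, 0.25, length.out = 70)
  truth <- species_mixture(wormlike_species(400, 40, 12, scale = 1),
                           background = 0.002)
  model0 <- mixture_intensity(q, truth)$intensity
  set.seed(77)
  sig <- 0.02 * model0
  crv <- saxs_curve(q, model0 + rnorm(70, 0, sig), sigma = sig)
  mk <- function() fit_spec(truth, free = list(
    "species1.cross_radius" = c(init = 8, lower = 1, upper = 40),
    "species1.scale" = c(init = 0.5, lower = 0, upper = 10)), seed = 3)
  cmp_same <- compare_models(crv, list(a = mk(), b = mk()), n_starts = 1)
  expect_equal(cmp_same$score[1L], cmp_same$score[2L], tolerance = 1e-9)
  expect_identical(cmp_same$model, c("a", "b"))
  # cylinder family on chain data ranks behind the chain family
  cyl <- species_mixture(cylinder_species(40, 400, scale = 1),
                         background = 0.002)
  spec_cyl <- fit_spec(cyl, free = list(
    "species1.radius" = c(init = 30, lower = 5, upper = 120),
    "species1.scale" = c(init = 0.5, lower = 0, upper = 10)), seed = 3)
  cmp <- compare_models(crv, list(chain = mk(), cylinder = spec_cyl),
                        n_starts = 2)
  expect_identical(cmp$model[1L], "chain")
})
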