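test_that("Guinier fits invert their defining equations exactly", {
  q <- seq(0.005, 0.05, length.out = 60)
  g <- guinier_fit(saxs_curve(q, 7 * exp(-q^2 * 256 / 3)))
  expect_equal(g$size, 16, tolerance = 1e-9)
  expect_equal(g$forward, 7, tolerance = 1e-9)
  expect_equal(g$r_squared, 1)
  r <- rodlike_guinier_fit(saxs_curve(q, (1 / q) * exp(-q^2 * 450)))
  expect_equal(r$size, 30, tolerance = 1e-9)
  expect_equal(r$forward, 1, tolerance = 1e-9)
})

test_that("size estimates are invariant under intensity rescaling", {
  q <- seq(0.004, 0.06, length.out = 80)
  p <- sphere_form_factor(q, 20.66)
  for (c0 in c(1e-3, 1, 250)) {
    f <- guinier_fit(saxs_curve(q, c0 * p))
    expect_equal(f$size, guinier_fit(saxs_curve(q, p))$size,
                 tolerance = 1e-10)
    expect_equal(f$forward, c0 * guinier_fit(saxs_curve(q, p))$forward,
                 tolerance = 1e-8)
  }
})

test_that("rod-like Guinier recovers cross-section radii of long cylinders", {
  q1 <- seq(0.002, 0.03, length.out = 120)
  c1 <- saxs_curve(q1, cylinder_intensity(q1, cylinder_species(108.9, 4000)))
  expect_equal(rodlike_guinier_fit(c1)$size, 77, tolerance = 0.02)
  q2 <- seq(0.005, 0.06, length.out = 120)
  c2 <- saxs_curve(q2, cylinder_intensity(q2, cylinder_species(42.4, 4000)))
  expect_equal(rodlike_guinier_fit(c2)$size, 30, tolerance = 0.02)
})

test_that("a fibril-like curve has no classical Guinier regime", {
  q <- seq(0.002, 0.03, length.out = 120)
  crv <- saxs_curve(q, cylinder_intensity(q, cylinder_species(108.9, 4000)))
  expect_error(guinier_fit(crv), "no Guinier regime")
})

test_that("Guinier Rg is unbiased within 2% under 1% counting noise", {
  q <- seq(0.004, 0.05, length.out = 100)
  p <- sphere_form_factor(q, 20.66)
  true_rg <- sqrt(3 / 5) * 20.66
  set.seed(42)
  rgs <- replicate(200, {
    noisy <- p * (1 + rnorm(length(p), 0, 0.01))
    guinier_fit(saxs_curve(q, noisy, sigma = 0.01 * p))$size
  })
  expect_lt(abs(mean(rgs) / true_rg - 1), 0.02)
})

test_that("two-population decomposition separates fibrils and protofibrils", {
  q <- seq(0.002, 0.06, length.out = 200)
  mix <- species_mixture(cylinder_species(108.9, 4000, scale = 1),
                        cylinder_species(42.4, 4000, scale = 1))
  tp <- two_population_rod_fit(mixture_intensity(q, mix))
  expect_true(tp$small_detected)
  expect_equal(tp$large$size, 77, tolerance = 0.1)
  expect_equal(tp$small$size, 30, tolerance = 0.1)
  # ordering is by Rc, independent of input species order
  mix_swapped <- species_mixture(cylinder_species(42.4, 4000, scale = 1),
                                 cylinder_species(108.9, 4000, scale = 1))
  tp2 <- two_population_rod_fit(mixture_intensity(q, mix_swapped))
  expect_gt(tp2$large$size, tp2$small$size)
  expect_equal(tp2$large$size, tp$large$size, tolerance = 1e-6)
})

test_that("a single rod population leaves the second fit undetected", {
  q <- seq(0.005, 0.06, length.out = 120)
  crv <- saxs_curve(q, cylinder_intensity(q, cylinder_species(42.4, 4000)))
  tp <- two_population_rod_fit(crv)
  expect_false(tp$small_detected)
  expect_null(tp$small)
})

test_that("two-population recovery holds across radius and scale ratios", {
  q <- seq(0.002, 0.08, length.out = 250)
  cases <- list(c(r1 = 90, r2 = 30, s1 = 1, s2 = 1),
                c(r1 = 80, r2 = 25, s1 = 3, s2 = 1),
                c(r1 = 120, r2 = 40, s1 = 2, s2 = 1),
                c(r1 = 70, r2 = 35, s1 = 1, s2 = 3))
  for (cs in cases) {
    mix <- species_mixture(
      cylinder_species(cs["r1"], 4000, scale = cs["s1"]),
      cylinder_species(cs["r2"], 4000, scale = cs["s2"]))
    tp <- two_population_rod_fit(mixture_intensity(q, mix))
    expect_true(tp$small_detected)
    expect_equal(tp$large$size, cs[["r1"]] / sqrt(2), tolerance = 0.1)
    expect_equal(tp$small$size, cs[["r2"]] / sqrt(2), tolerance = 0.1)
  }
})

test_that("Kratky shapes: bell for globular, plateau for coils, rising for flat", {
  q <- seq(0.01, 0.45, length.out = 100)
  bell <- kratky_shape_score(saxs_curve(q, sphere_form_factor(q, 20)))
  expect_identical(bell$label, "bell")
  expect_gt(bell$score, 0.5)
  coil <- kratky_shape_score(saxs_curve(q, oracle_debye_coil(q, 30)))
  expect_identical(coil$label, "plateau")
  # Debye-coil Kratky plateau sits at 2 * scale / Rg^2
  k <- kratky_transform(saxs_curve(q, 5 * oracle_debye_coil(q, 30)))
  expect_equal(mean(tail(k$q2i, 10)), 2 * 5 / 30^2, tolerance = 0.02)
  flat <- kratky_shape_score(saxs_curve(q, rep(1, 100)))
  expect_identical(flat$label, "rising")
  expect_error(kratky_shape_score(saxs_curve(q[1:10], rep(1, 10))),
               "20 points")
  expect_error(kratky_shape_score(saxs_curve(q, rep(c(1, -1), 50))),
               "positive")
})
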