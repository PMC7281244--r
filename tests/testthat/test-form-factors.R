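test_that("sphere form factor: normalization, Guinier radius, first zero", {
  expect_equal(sphere_form_factor(1e-9, 20.66), 1)
  q <- seq(0.004, 0.05, length.out = 80)
  p <- sphere_form_factor(q, 20.66)
  expect_true(all(p >= 0 & p <= 1))
  # Guinier fit recovers Rg = sqrt(3/5) R
  fit <- guinier_fit(saxs_curve(q, p))
  expect_equal(fit$size, sqrt(3 / 5) * 20.66, tolerance = 0.0125)
  # first zero at Q R = smallest positive root of tan(x) = x
  x0 <- oracle_sphere_first_zero()
  expect_equal(x0, 4.4934, tolerance = 1e-4)
  R <- 30
  qz <- seq(x0 / R * 0.9, x0 / R * 1.1, length.out = 4001)
  pz <- sphere_form_factor(qz, R)
  expect_equal(qz[which.min(pz)] * R, x0, tolerance = 1e-3)
  expect_error(sphere_form_factor(q, -1), "positive")
})

test_that("cylinder intensity matches the brute-force orientation oracle", {
  q <- seq(0.005, 0.25, length.out = 50)
  for (geom in list(c(40, 300), c(38, 2000), c(108.9, 4000))) {
    p <- cylinder_intensity(q, cylinder_species(geom[1], geom[2]))
    b <- oracle_cylinder_P(q, geom[1], geom[2])
    expect_lt(max(abs(p - b)) / max(b), 1e-3)
  }
})

test_that("polydisperse cylinder matches the brute-force double quadrature", {
  q <- seq(0.005, 0.2, length.out = 50)
  p <- cylinder_intensity(q, cylinder_species(40, 300, polydispersity = 0.25))
  b <- oracle_polydisperse_P(q, 40, 0.25, 300)
  expect_lt(max(abs(p - b)) / max(b), 1e-3)
})

test_that("polydispersity -> 0 recovers the monodisperse cylinder", {
  q <- seq(0.005, 0.2, length.out = 40)
  mono <- cylinder_intensity(q, cylinder_species(40, 300))
  near <- cylinder_intensity(q, cylinder_species(40, 300,
                                                 polydispersity = 1e-4))
  expect_lt(max(abs(near - mono) / mono), 1e-3)
})

test_that("cylinder edge behaviour: zero scale, long-rod Guinier limit", {
  q <- seq(0.005, 0.05, length.out = 30)
  expect_equal(cylinder_intensity(q, cylinder_species(40, 300, scale = 0)),
               rep(0, 30))
  # long monodisperse cylinder: cross-section Rc = R / sqrt(2)
  qf <- seq(0.002, 0.04, length.out = 100)
  crv <- saxs_curve(qf, cylinder_intensity(qf, cylinder_species(60, 4000)))
  fit <- rodlike_guinier_fit(crv)
  expect_equal(fit$size, 60 / sqrt(2), tolerance = 0.02)
})

test_that("worm-like chain: coil limit, rod limit, normalization", {
  # flexible limit matches the Debye coil with Rg^2 = L b / 6 within 5%
  L <- 10000; b <- 20
  rg <- sqrt(L * b / 6)
  q <- 10^seq(log10(0.3 / rg), log10(0.8 / b), length.out = 40)
  wl <- wormlike_intensity(q, wormlike_species(L, b, cross_radius = 0))
  expect_lt(max(abs(wl / oracle_debye_coil(q, rg) - 1)), 0.05)
  # thin-chain high-Q regime: local log-log slope -> -1
  qh <- c(0.8, 1.0, 1.25)
  wh <- wormlike_intensity(qh, wormlike_species(L, b, cross_radius = 0))
  slopes <- diff(log(wh)) / diff(log(qh))
  expect_equal(mean(slopes), -1, tolerance = 0.03)
  # forward limit equals the scale
  expect_equal(
    wormlike_intensity(1e-8, wormlike_species(400, 40, 9.5, scale = 3.7)),
    3.7, tolerance = 1e-6)
  expect_error(wormlike_species(30, 40), "contour_length")
})

test_that("Debye formula from coordinates: closed forms and errors", {
  one <- atomic_structure(data.frame(element = "C", x = 0, y = 0, z = 0),
                          shell_thickness = 0)
  expect_equal(debye_intensity_from_structure(c(0.05, 0.3), one), c(1, 1))
  # two identical point atoms distance d apart: P = (1 + sinc(Qd))/2
  d <- 10
  two <- atomic_structure(data.frame(element = c("O", "O"),
                                     x = c(0, d), y = 0, z = 0),
                          shell_thickness = 0)
  q <- c(0.05, 0.1, 0.3, 0.6)
  expect_equal(debye_intensity_from_structure(q, two, bin = 0.01),
               (1 + sin(q * d) / (q * d)) / 2, tolerance = 1e-3)
  bad <- atomic_structure(data.frame(element = "XX", x = 0, y = 0, z = 0))
  expect_error(debye_intensity_from_structure(0.1, bad), "XX")
})

test_that("mixture intensity is additive, linear in scale, needs species", {
  q <- seq(0.005, 0.1, length.out = 40)
  c1 <- cylinder_species(80, 2000, scale = 1.5)
  c2 <- cylinder_species(30, 2000, scale = 0.5)
  mix <- species_mixture(c1, c2, background = 0.01)
  total <- mixture_intensity(q, mix)$intensity
  expect_equal(total,
               cylinder_intensity(q, c1) + cylinder_intensity(q, c2) + 0.01,
               tolerance = 1e-12)
  # doubling every scale doubles intensity minus background
  mix2 <- species_mixture(cylinder_species(80, 2000, scale = 3),
                          cylinder_species(30, 2000, scale = 1),
                          background = 0.01)
  expect_equal(mixture_intensity(q, mix2)$intensity - 0.01,
               2 * (total - 0.01), tolerance = 1e-10)
  expect_error(species_mixture(background = 0), "at least one")
})

test_that("all form factors are normalized and non-negative", {
  qtiny <- 1e-8
  q <- seq(0.005, 0.4, length.out = 60)
  species <- list(cylinder_species(40, 500, 0.2, scale = 2),
                  wormlike_species(400, 40, 9.5, scale = 0.7),
                  sphere_species(25, scale = 1.3))
  for (s in species) {
    expect_equal(species_intensity(qtiny, s), s$scale, tolerance = 1e-4)
    expect_true(all(species_intensity(q, s) >= 0))
  }
})
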