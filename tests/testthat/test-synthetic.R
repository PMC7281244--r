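test_that("simulate_saxs: exact at zero noise, deterministic given seed", {
  mix <- species_mixture(sphere_species(20, scale = 1), background = 0.001)
  q <- seq(0.01, 0.2, length.out = 40)
  clean <- simulate_saxs(mix, q, noise = 0, seed = 1)
  expect_equal(clean$intensity, mixture_intensity(q, mix)$intensity)
  expect_null(clean$sigma)
  a <- simulate_saxs(mix, q, noise = 0.02, seed = 7)
  b <- simulate_saxs(mix, q, noise = 0.02, seed = 7)
  expect_identical(a$intensity, b$intensity)
  c2 <- simulate_saxs(mix, q, noise = 0.02, seed = 8)
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("counting-noise model is calibrated: residual variance matches sigma^2", {
  mix <- species_mixture(sphere_species(20, scale = 1), background = 0.001)
  q <- seq(0.01, 0.2, length.out = 40)
  model <- mixture_intensity(q, mix)$intensity
  reps <- vapply(1:500, function(s)
    simulate_saxs(mix, q, noise = 0.05, seed = s)$intensity - model,
    numeric(length(q)))
  sig <- simulate_saxs(mix, q, noise = 0.05, seed = 1)$sigma
  expect_lt(max(abs(rowMeans(reps))/ sig), 0.2)        # mean ~ 0
  expect_lt(abs(mean(apply(reps, 1, var) / sig^2) - 1), 0.05)
  # chi-square per point ~ 1 against the claimed noise model
  chi2 <- mean((reps / sig)^2)
  expect_equal(chi2, 1, tolerance = 0.05)
})

test_that("fibrillation trajectories are bounded and follow the encoded
           orderings", {
  for (row in seq_len(nrow(scenario_table()))) {
    tab <- scenario_table()[row, ]
    cfg <- scenario_config(tab$protein, tab$trehalose_mM, tab$nacl_mM,
                           seed = row)
    f <- fibrillation_timecourse(cfg)
    expect_true(all(f >= 0 & f <= 1))
  }
  # lysozyme + trehalose, no salt: essentially no fibrillation for 240 min
  cfg_blocked <- scenario_config("lysozyme", 150, 0, seed = 1)
  expect_true(all(fibrillation_timecourse(cfg_blocked) < 0.05))
  # NaCl collapses the insulin lag even with trehalose
  half_time <- function(cfg) {
    f <- fibrillation_timecourse(cfg)
    cfg$time_grid[which(f >= max(f) / 2)[1L]]
  }
  expect_lt(half_time(scenario_config("insulin", 300, 100, seed = 1)),
            half_time(scenario_config("insulin", 300, 0, seed = 1)) - 100)
  expect_error(scenario_config("insulin", 150, 0, seed = 1),
               "unknown condition")
})

test_that("CR spectra peak at the free and bound positions", {
  f0 <- simulate_cr_spectrum(0)
  expect_equal(f0$wavelength[which.max(f0$absorbance)], 505,
               tolerance = 3 / 505)
  f1 <- simulate_cr_spectrum(1)
  expect_equal(f1$wavelength[which.max(f1$absorbance)], 540,
               tolerance = 3 / 540)
  expect_error(simulate_cr_spectrum(1.2), "\\[0, 1\\]")
})

test_that("fixture bundle is reproducible with a complete manifest", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  q <- seq(0.01, 0.2, length.out = 30)
  # atomic-structure scenarios are exercised once (they are the slow part)
  m1 <- generate_fixtures(d1, seed = 5, q_grid = q, n_replicates = 3)
  m2 <- generate_fixtures(d2, seed = 5, q_grid = q, n_replicates = 3)
  files <- list.files(d1)
  expect_true("manifest.json" %in% files)
  expect_length(grep("\\.dat$", files), 6L)
  expect_length(grep("\\.csv$", files), nrow(scenario_table()))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # manifest records generating parameters for every file
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_setequal(
    vapply(man$saxs, `[[`, character(1L), "file"),
    grep("\\.dat$", files, value = TRUE))
  expect_true(all(vapply(man$saxs, function(x)
    !is.null(x$species) && !is.null(x$seed), logical(1L))))
  radii <- unlist(lapply(man$saxs$insulin_final$species,
                         function(s) s$radius))
  expect_equal(radii, 38)
})
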