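test_that("beta_ratio geometry on single and symmetric two-band spectra", {
  wl <- 400:650
  # pure free-dye band: ratio equals the band's own 538/505 value, < 1
  free_only <- absorbance_spectrum(wl, exp(-(wl - 505)^2 / (2 * 19^2)))
  r <- beta_ratio(free_only)
  expect_lt(as.numeric(r), 1)
  expect_equal(as.numeric(r),
               exp(-(538 - 505)^2 / (2 * 19^2)) / 1, tolerance = 1e-6)
  # equal-amplitude equal-width bands at exactly 505 and 538: ratio = 1
  sym <- absorbance_spectrum(wl, exp(-(wl - 505)^2 / (2 * 20^2)) +
                               exp(-(wl - 538)^2 / (2 * 20^2)))
  expect_equal(as.numeric(beta_ratio(sym)), 1, tolerance = 1e-9)
  # errors: wavelength outside grid, non-positive denominator
  expect_error(beta_ratio(absorbance_spectrum(400:500, rep(1, 101))),
               "outside")
  expect_error(beta_ratio(absorbance_spectrum(wl, rep(0, length(wl)))),
               "not positive")
})

test_that("beta_ratio is dilution-invariant and monotone in bound fraction", {
  sp <- simulate_cr_spectrum(0.4)
  r1 <- as.numeric(beta_ratio(sp))
  diluted <- absorbance_spectrum(sp$wavelength, 0.213 * sp$absorbance)
  expect_equal(as.numeric(beta_ratio(diluted)), r1, tolerance = 1e-12)
  fs <- seq(0, 1, by = 0.05)
  ratios <- vapply(fs, function(f)
    as.numeric(beta_ratio(simulate_cr_spectrum(f))), numeric(1L))
  expect_true(all(diff(ratios) > 0))
})

test_that("area ratio equals fitted band intensity ratio where defined", {
  wl <- 400:650
  # two equal Gaussians: both ratios exactly 1
  eq <- absorbance_spectrum(wl, exp(-(wl - 505)^2 / (2 * 21^2)) +
                              exp(-(wl - 540)^2 / (2 * 21^2)))
  ar <- area_ratio(eq)
  expect_equal(ar$area_ratio, 1, tolerance = 1e-6)
  expect_equal(ar$intensity_ratio, 1, tolerance = 1e-6)
  # zero bound band: area ratio 0
  none <- area_ratio(simulate_cr_spectrum(0))
  expect_equal(none$area_ratio, 0, tolerance = 1e-6)
  # across the kinetic sweep the two ratios agree within 10%
  for (f in seq(0.1, 0.9, by = 0.2)) {
    a <- area_ratio(simulate_cr_spectrum(f, noise = 0.002,
                                         seed = round(1000 * f)))
    expect_lt(abs(a$relative_diff), 0.1)
  }
})

test_that("kinetic trace assembly averages replicates with sqrt(n) errors", {
  mk <- function(t, rep, noise, seed)
    simulate_cr_spectrum(0.5, noise = noise, seed = seed, time_label = t,
                         replicate = rep)
  # single replicate: no sem
  single <- build_kinetic_trace(list(mk(0, 1, 0, 1), mk(30, 1, 0, 1)))
  expect_null(single$sem)
  # 9 identical replicates: sem exactly 0
  same <- build_kinetic_trace(
    lapply(1:9, function(r) mk(0, r, 0, 1)))
  expect_equal(same$sem, 0)
  # mismatched replicate counts across times is an error
  expect_error(build_kinetic_trace(list(mk(0, 1, 0, 1), mk(0, 2, 0, 2),
                                        mk(30, 1, 0, 3))),
               "share time labels")
  # sqrt(n) law: sem of 9 noisy replicates ~ sd of single ratios / 3
  ratios <- vapply(1:300, function(s)
    as.numeric(beta_ratio(simulate_cr_spectrum(0.5, noise = 0.004,
                                               seed = s))), numeric(1L))
  sd1 <- sd(ratios)
  traces <- lapply(1:40, function(g)
    build_kinetic_trace(lapply(1:9, function(r)
      mk(0, r, 0.004, 1000 * g + r))))
  sems <- vapply(traces, function(tr) tr$sem[1L], numeric(1L))
  expect_lt(abs(mean(sems) / (sd1 / 3) - 1), 0.3)
})

test_that("kinetic traces round-trip through CSV", {
  tr <- kinetic_trace(c(0, 30, 60), c(0.3, 0.9, 2.1), sem = c(0.02, 0.03,
                                                              0.05))
  f <- tempfile(fileext = ".csv")
  write_kinetic_trace_csv(tr, f)
  back <- read_kinetic_trace_csv(f)
  expect_equal(back$time, tr$time)
  expect_equal(back$beta_ratio, tr$beta_ratio)
  expect_equal(back$sem, tr$sem)
})

test_that("spectra CSV reader splits times and replicates", {
  f <- tempfile(fileext = ".csv")
  d <- do.call(rbind, lapply(c(0, 30), function(t0)
    do.call(rbind, lapply(1:2, function(r)
      data.frame(wavelength_nm = 480:560,
                 absorbance = simulate_cr_spectrum(
                   0.3, 480:560, noise = 0.001,
                   seed = t0 + r)$absorbance,
                 time_min = t0, replicate = r)))))
  utils::write.csv(d, f, row.names = FALSE)
  sps <- read_spectra_csv(f)
  expect_length(sps, 4L)
  tr <- build_kinetic_trace(sps)
  expect_equal(tr$time, c(0, 30))
  expect_equal(tr$n_replicates, 2L)
})
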