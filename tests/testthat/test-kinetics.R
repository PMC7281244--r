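test_that("noise-free logistic parameters are recovered exactly", {
  t <- seq(0, 300, by = 15)
  y <- 0.3 + (2.1 - 0.3) / (1 + exp(-0.06 * (t - 120)))
  fit <- fit_sigmoid(kinetic_trace(t, y))
  expect_equal(fit$baseline, 0.3, tolerance = 1e-5)
  expect_equal(fit$plateau, 2.1, tolerance = 1e-5)
  expect_equal(fit$t_half, 120, tolerance = 1e-4)
  expect_equal(fit$rate, 0.06, tolerance = 1e-5)
  expect_equal(fit$lag_time, 120 - 2 / 0.06, tolerance = 1e-3)
  expect_false(fit$censored)
  expect_error(fit_sigmoid(kinetic_trace(c(0, 50, 100), c(0, 1, 2))),
               "6 time points")
})

test_that("lag and midpoint shift exactly with a time shift", {
  t <- seq(0, 300, by = 15)
  y <- 0.2 + 1.5 / (1 + exp(-0.05 * (t - 100)))
  f0 <- fit_sigmoid(kinetic_trace(t, y))
  dt <- 47
  f1 <- fit_sigmoid(kinetic_trace(t + dt, y))
  expect_equal(f1$t_half, f0$t_half + dt, tolerance = 1e-3)
  expect_equal(f1$lag_time, f0$lag_time + dt, tolerance = 1e-3)
  expect_equal(f1$rate, f0$rate, tolerance = 1e-5)
})

test_that("ratio rescaling scales levels but not lag or rate", {
  t <- seq(0, 300, by = 15)
  y <- 0.2 + 1.5 / (1 + exp(-0.05 * (t - 100)))
  f0 <- fit_sigmoid(kinetic_trace(t, y))
  c0 <- 3.7
  f1 <- fit_sigmoid(kinetic_trace(t, c0 * y))
  expect_equal(f1$baseline, c0 * f0$baseline, tolerance = 1e-5)
  expect_equal(f1$plateau, c0 * f0$plateau, tolerance = 1e-5)
  expect_equal(f1$lag_time, f0$lag_time, tolerance = 1e-3)
  expect_equal(f1$rate, f0$rate, tolerance = 1e-5)
})

test_that("flat and unfinished traces are flagged censored", {
  t <- seq(0, 240, by = 20)
  flat <- fit_sigmoid(kinetic_trace(t, rep(0.31, length(t)) +
                                      0.001 * sin(t)))
  expect_true(flat$censored)
  expect_true(flat$flat)
  # rise that has not reached plateau: censored but not flat
  y <- 0.2 + 1.5 / (1 + exp(-0.02 * (t - 230)))
  unfinished <- fit_sigmoid(kinetic_trace(t, y))
  expect_true(unfinished$censored)
})

test_that("identical conditions show zero differences and no blocking", {
  t <- seq(0, 300, by = 15)
  y <- 0.2 + 1.5 / (1 + exp(-0.05 * (t - 100)))
  f <- fit_sigmoid(kinetic_trace(t, y))
  cmp <- compare_conditions(list(a = f, b = f), n_boot = 25, seed = 3)
  expect_equal(cmp$d_lag[cmp$condition == "b"], 0, tolerance = 1e-9)
  expect_equal(cmp$d_plateau[cmp$condition == "b"], 0, tolerance = 1e-9)
  expect_false(any(cmp$blocked))
})

test_that("lag recovery from replicated noisy traces is within 10 minutes", {
  cfg0 <- scenario_config("insulin", 0, 0, seed = 1)
  truth <- fit_sigmoid(noise_free_trace(cfg0))
  lags <- vapply(1:100, function(r) {
    cfg <- scenario_config("insulin", 0, 0, seed = 20000 + r)
    fit_sigmoid(simulate_cr_kinetics(cfg, n_replicates = 9))$lag_time
  }, numeric(1L))
  expect_lt(abs(median(lags) - truth$lag_time), 10)
  expect_lt(mean(abs(lags - truth$lag_time) > 10), 0.25)
})

test_that("trehalose without salt blocks lysozyme; insulin plateau drops ~10%", {
  ref <- fit_sigmoid(simulate_cr_kinetics(
    scenario_config("lysozyme", 0, 0, seed = 21)))
  treh <- fit_sigmoid(simulate_cr_kinetics(
    scenario_config("lysozyme", 150, 0, seed = 22)))
  cmp <- compare_conditions(list(reference = ref, trehalose = treh),
                            n_boot = 25, seed = 5)
  expect_true(cmp$blocked[cmp$condition == "trehalose"])
  expect_false(cmp$blocked[cmp$condition == "reference"])

  ins0 <- fit_sigmoid(simulate_cr_kinetics(
    scenario_config("insulin", 0, 0, seed = 23)))
  ins_t <- fit_sigmoid(simulate_cr_kinetics(
    scenario_config("insulin", 300, 0, seed = 24)))
  drop <- 1 - ins_t$plateau / ins0$plateau
  expect_equal(drop, 0.10, tolerance = 0.5)
  expect_gt(ins_t$lag_time, ins0$lag_time + 100)
})
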