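test_that("O-U sampler reproduces the closed-form autocorrelation and variance", {
  tau <- 2; dt <- 0.1; n <- 1e5
  reg <- flow_regime(mu = 82.8, sigma = 0.58, tau_h = tau)
  ser <- sample_water_table(reg, seq(0, (n - 1) * dt, by = dt), seed = 11)
  x <- ser$level
  rho1 <- cor(x[-1], x[-n])
  expect_equal(rho1, exp(-dt / tau), tolerance = 3 / sqrt(n) / exp(-dt / tau))

  # stationary variance, with an effective sample size for correlated data
  rho <- exp(-dt / tau)
  neff <- n * (1 - rho) / (1 + rho)
  se_var <- reg$sigma^2 * sqrt(2 / neff)
  expect_lt(abs(var(x) - reg$sigma^2), 3 * se_var)
})

test_that("autocorrelation decays as exp(-lag/tau) across correlation times", {
  dt <- 0.05; n <- 4e4
  for (tau in c(0.5, 2, 10)) {
    ser <- sample_water_table(flow_regime(80, 1, tau),
                              seq(0, (n - 1) * dt, by = dt), seed = 5)
    for (lag_steps in c(2L, 5L)) {
      L <- lag_steps * dt
      emp <- cor(ser$level[-(1:lag_steps)], ser$level[1:(n - lag_steps)])
      expect_equal(emp, exp(-L / tau), tolerance = 0.05,
                   label = sprintf("tau=%g lag=%g", tau, L))
    }
  }
})

test_that("degenerate and white-noise limits behave", {
  grid <- seq(0, 10, by = 0.1)
  ser <- sample_water_table(flow_regime(82.8, 1e-12, 2), grid, seed = 1)
  expect_true(all(abs(ser$level - 82.8) < 1e-9))

  # tau_h = 0: i.i.d. draws, negligible lag-1 correlation
  ser0 <- sample_water_table(flow_regime(82.8, 0.58, 0),
                             seq(0, 999.9, by = 0.1), seed = 2)
  n <- nrow(ser0)
  expect_lt(abs(cor(ser0$level[-1], ser0$level[-n])), 3 / sqrt(n))
})

test_that("sampler is deterministic in the seed and validates input", {
  grid <- seq(0, 5, by = 0.05)
  reg <- flow_regime(82.8, 0.58, 2)
  expect_identical(sample_water_table(reg, grid, seed = 42),
                   sample_water_table(reg, grid, seed = 42))
  expect_error(sample_water_table(reg, c(0, 0.1, 0.3), seed = 1), "uniform")
  expect_error(flow_regime(82.8, -1, 0), "sigma")
  expect_error(flow_regime(82.8, 0.58, -1), "tau_h")
})

test_that("regime estimation round-trips simulated records", {
  grid <- seq(0, 0.1 * (1e5 - 1), by = 0.1)
  ser <- sample_water_table(flow_regime(82.8, 0.58, 2), grid, seed = 9)
  est <- estimate_regime(ser)
  expect_equal(est$mu, 82.8, tolerance = 0.05 * 82.8)
  expect_equal(est$sigma, 0.58, tolerance = 0.05)
  expect_equal(est$tau_h, 2, tolerance = 0.1 * 2)

  # i.i.d. Gaussian input: correlation time clamps to ~0
  iid <- sample_water_table(flow_regime(82.8, 0.58, 0),
                            seq(0, 499.9, by = 0.1), seed = 3)
  expect_lt(estimate_regime(iid)$tau_h, 0.05)

  expect_error(estimate_regime(flow_series(seq(0, 9.9, by = 0.1),
                                           rep(82.8, 100))), "constant")
  expect_error(estimate_regime(flow_series(c(0, 1), c(1, 2))), "at least")
})

test_that("Gaussianity test holds its level and has power", {
  # level: ~1% rejections at alpha = 0.01 under the null
  n_rep <- 400L
  grid <- seq(0, 99.9, by = 0.1)
  rej <- vapply(seq_len(n_rep), function(r) {
    ser <- sample_water_table(flow_regime(80, 1, 0), grid, seed = 100 + r)
    gaussian_fit_test(ser)$p_value < 0.01
  }, logical(1))
  band <- 3 * sqrt(0.01 * 0.99 / n_rep)
  expect_lt(abs(mean(rej) - 0.01), band + 1e-12)

  # power: exponential levels are rejected nearly always at n = 500
  rej_exp <- vapply(seq_len(100L), function(r) {
    set.seed(500 + r)
    ser <- flow_series(seq(0, 49.9, by = 0.1), rexp(500))
    gaussian_fit_test(ser)$p_value < 0.01
  }, logical(1))
  expect_gt(mean(rej_exp), 0.95)

  expect_error(gaussian_fit_test(flow_series(seq(0, 9.9, by = 0.1),
                                             rep(1, 100))), "constant")
  expect_identical(gaussian_fit_test(sample_water_table(
    flow_regime(80, 1, 0), grid, 1))$method, "Anderson-Darling")
})

test_that("drifting regime traces the sine at segment midpoints", {
  base <- flow_regime(82.8, 0.58, 0)
  flat <- make_drifting_regime(base, 0, 0, period = 60, horizon = 60,
                               n_segments = 6)
  expect_true(all(vapply(flat$regimes, function(r) r$mu == 82.8, logical(1))))

  seg <- make_drifting_regime(base, 1.2, 0.1, period = 60, horizon = 60,
                              n_segments = 60)
  mus <- vapply(seg$regimes, function(r) r$mu, numeric(1))
  mids <- (seq_len(60) - 0.5)
  expect_equal(mus, 82.8 + 1.2 * sin(2 * pi * mids / 60))
  expect_equal(max(abs(mus - 82.8)), 1.2, tolerance = 0.01)

  one <- make_drifting_regime(base, 1.2, 0, 60, 60, n_segments = 1)
  expect_length(one$regimes, 1L)
  expect_equal(one$regimes[[1]]$mu, 82.8 + 1.2 * sin(2 * pi * 30 / 60))

  expect_error(make_drifting_regime(base, 0, 0.6, 60, 60, 10), "sd_amplitude")
})

test_that("segmented regimes validate coverage and lookup works", {
  r1 <- flow_regime(82, 0.5, 0); r2 <- flow_regime(83, 0.6, 0)
  seg <- segmented_regime(c(0, 30), c(30, 60), list(r1, r2))
  expect_equal(riparia:::regime_at(seg, 10)$mu, 82)
  expect_equal(riparia:::regime_at(seg, 45)$mu, 83)
  expect_error(segmented_regime(c(0, 40), c(30, 60), list(r1, r2)),
               "contiguous")
  expect_error(segmented_regime(c(0, 30), c(0, 60), list(r1, r2)), "t_start")
})

test_that("flow series round-trips through delimited text", {
  ser <- sample_water_table(flow_regime(82.8, 0.58, 2),
                            seq(0, 9.9, by = 0.1), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_series(ser, path, meta = list(units = "m, yr"))
  back <- read_flow_series(path)
  expect_equal(back$level, ser$level)
  expect_equal(back$time, ser$time)
})
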