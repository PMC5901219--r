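test_that("noise-off simulation matches the closed-form logistic solution", {
  reg <- flow_regime(82.8, 1e-12, 0)
  ens <- simulate_cohort(birch, reg, eta = 83.03, t_end = 1, dt = 0.01,
                         n_paths = 3, seed = 1)
  n_Tf <- ens$n[nrow(ens$n), 1]
  expect_equal(n_Tf,
               logistic_solution(1, birch$lambda, birch$a_f, eta_prime1,
                                 birch$epsilon),
               tolerance = 1e-6)
})

test_that("white-noise ensemble matches the analytic logit moments", {
  ens <- simulate_cohort(birch, luan_regime, eta = 83.03, t_end = 1,
                         dt = 0.01, n_paths = 5000, seed = 21)
  ln <- logit(ens$n[nrow(ens$n), ])
  fm <- formative_moments(1, birch, eta_prime1, 0.58)
  n <- length(ln)
  expect_lt(abs(mean(ln) - fm$mean), 3 * sd(ln) / sqrt(n))
  expect_lt(abs(var(ln) - fm$variance), 3 * fm$variance * sqrt(2 / (n - 1)))
  # Gaussianity of logit n inside the formative stage
  mid <- which.min(abs(ens$time - 0.5))
  expect_gt(nortest::ad.test(logit(ens$n[mid, ]))$p.value, 0.01)
})

test_that("decline-stage ensemble tracks the analytic log moments", {
  ens <- simulate_cohort(birch, luan_regime, eta = 83.03, t_end = 3,
                         dt = 0.01, n_paths = 4000, seed = 8)
  lg <- log(ens$n[nrow(ens$n), ])
  c2 <- continuity_constant(birch, eta_prime1, 0.58)
  dm <- decline_moments(3, birch, eta_prime1, 0.58, c2)
  n <- length(lg)
  expect_lt(abs(mean(lg) - dm$mean), 3 * sd(lg) / sqrt(n) + 2e-3)
  # pathwise paths inherit the formative-stage dispersion of log n(T_f) on
  # top of the decline law's own diffusion (the analytic decline variance
  # restarts at 0 under distribution-level continuity); the pathwise
  # prediction adds Var[log n(T_f)] computed against the formative law
  fm <- formative_moments(1, birch, eta_prime1, 0.58)
  s <- sqrt(fm$variance)
  e2 <- integrate(function(z) plogis(fm$mean + s * z, log.p = TRUE)^2 * dnorm(z),
                  -Inf, Inf, rel.tol = 1e-10)$value
  v_inherit <- e2 - c2^2
  v_total <- dm$variance + v_inherit
  expect_lt(abs(var(lg) - v_total), 3 * v_total * sqrt(2 / (n - 1)) + 1e-4)
})

test_that("paths stay in (0, 1] and ensembles are seed-deterministic", {
  ens <- simulate_cohort(birch, luan_regime, eta = 84.67, t_end = 5,
                         dt = 0.01, n_paths = 200, seed = 3)
  expect_true(all(ens$n > 0 & ens$n <= 1))
  ens2 <- simulate_cohort(birch, luan_regime, eta = 84.67, t_end = 5,
                          dt = 0.01, n_paths = 200, seed = 3)
  expect_identical(ens$n, ens2$n)
  expect_error(simulate_cohort(birch, luan_regime, 83, t_end = 1, dt = 0.05,
                               n_paths = 2, seed = 1), "coarse")
  expect_error(simulate_cohort(birch, flow_regime(82.8, 0.58, 0.5), 83,
                               t_end = 1, dt = 0.01, n_paths = 2, seed = 1,
                               mode = "ou_pathwise"), "coarse")
})

test_that("colored-noise paths inflate the variance beyond the white-noise law", {
  v1 <- formative_moments(1, birch, eta_prime1, 0.58, tau_h = 0)$variance
  ens <- simulate_cohort(birch, flow_regime(82.8, 0.58, 0.5), eta = 83.03,
                         t_end = 1, dt = 0.005, n_paths = 2000, seed = 13,
                         mode = "ou_pathwise")
  v_emp <- var(logit(ens$n[nrow(ens$n), ]))
  expect_gt(v_emp, v1)
})

test_that("frozen-sensitivity discretization converges under step halving", {
  c2 <- continuity_constant(birch, eta_prime1, 0.58)
  dm <- decline_moments(2, birch, eta_prime1, 0.58, c2)
  errs <- vapply(c(0.01, 0.005), function(dt) {
    ens <- simulate_cohort(birch, luan_regime, 83.03, t_end = 2, dt = dt,
                           n_paths = 3000, seed = 17, record_dt = 0.1)
    abs(mean(log(ens$n[nrow(ens$n), ])) - dm$mean)
  }, numeric(1))
  # halving the step must not worsen the bias beyond Monte-Carlo jitter
  expect_lt(errs[2], errs[1] + 3 * sqrt(dm$variance / 3000))
})

test_that("stopping times find the deterministic crossing and censor correctly", {
  # noise off: crossing solves the decline closed form
  reg0 <- flow_regime(82.8, 1e-12, 0)
  ens <- simulate_cohort(birch, reg0, 83.03, t_end = 250, dt = 0.01,
                         n_paths = 2, seed = 1, record_dt = 0.1)
  st <- stopping_times(ens, n_e = 0.01)
  c2_det <- log(logistic_solution(1, birch$lambda, birch$a_f, eta_prime1,
                                  birch$epsilon))
  M_det <- eta_prime1^2  # sigma ~ 0
  td_det <- mean_lifespan(birch, eta_prime1, 1e-12, n_e = 0.01,
                          c2 = c2_det)$Td
  expect_false(any(st$censored))
  expect_lt(max(abs(st$time - td_det)), 0.1 + 1e-9)

  # n_e = 0 can never be crossed: all paths censored
  st0 <- stopping_times(ens, n_e = 0)
  expect_true(all(st0$censored))
  expect_error(stopping_times(ens, n_e = 0.2), "epsilon")

  # censored fraction shrinks as the horizon extends
  mk <- function(h) {
    e <- simulate_cohort(birch, luan_regime, 84.3, t_end = h, dt = 0.01,
                         n_paths = 300, seed = 5, record_dt = 0.2)
    mean(stopping_times(e, 0.01)$censored)
  }
  expect_lte(mk(60), mk(20))
})

test_that("ensembles export to a long columnar table", {
  ens <- simulate_cohort(birch, luan_regime, 83.03, t_end = 0.1, dt = 0.01,
                         n_paths = 3, seed = 2)
  tab <- ensemble_table(ens)
  expect_identical(nrow(tab), length(ens$time) * 3L)
  expect_equal(tab$n[tab$path == 2], ens$n[, 2])
  path <- withr::local_tempfile(fileext = ".csv")
  write_table_with_meta(tab, path, meta = list(seed = ens$seed, mode = ens$mode))
  back <- read_table_with_meta(path)
  expect_equal(back$n, tab$n)
  expect_identical(attr(back, "meta")$mode, "wgn_exact")
})

test_that("segmented regimes switch the driving statistics mid-simulation", {
  seg <- segmented_regime(c(0, 0.5), c(0.5, 1),
                          list(flow_regime(83.03, 1e-12, 0),
                               flow_regime(84.03, 1e-12, 0)))
  ens <- simulate_cohort(birch, seg, eta = 83.03, t_end = 1, dt = 0.01,
                         n_paths = 1, seed = 1)
  # first half: zero divergence, growth at lambda; second half: divergence 1
  y <- logit(ens$n[, 1])
  g1 <- (y[51] - y[1]) / 0.5
  g2 <- (y[101] - y[51]) / 0.5
  expect_equal(g1, birch$lambda, tolerance = 1e-6)
  expect_equal(g2, birch$lambda - birch$a_f * 1, tolerance = 1e-6)
})
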