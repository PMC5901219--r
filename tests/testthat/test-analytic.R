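test_that("formative moments reproduce the worked white-noise values", {
  m0 <- formative_moments(0, birch, eta_prime1, 0.58)
  expect_equal(m0$mean, logit(0.05))
  expect_equal(m0$mean, -2.944439, tolerance = 1e-6)
  expect_identical(m0$variance, 0)

  m1 <- formative_moments(1, birch, eta_prime1, 0.58)
  expect_equal(m1$M, 0.38930, tolerance = 1e-10)
  expect_equal(m1$mean, 0.104804, tolerance = 1e-6)
  expect_equal(m1$variance, 0.01709086, tolerance = 1e-6)
  expect_error(formative_moments(2, birch, eta_prime1, 0.58), "T_f")
})

test_that("eta_prime and sigma enter the white-noise law only through M and Sigma^2", {
  # swap (eta', sigma) -> (sigma, eta'): M and Sigma^2 are preserved
  a <- formative_moments(0.7, birch, -0.23, 0.58)
  b <- formative_moments(0.7, birch, 0.58, 0.23)
  expect_equal(b$mean, a$mean)
  expect_equal(b$variance, a$variance)
  # mean increases iff lambda - a_f M > 0
  for (ep in c(0, 0.5, 2, 3)) {
    mo <- vapply(c(0.4, 0.8), function(t) {
      formative_moments(t, birch, ep, 0.58)$mean
    }, numeric(1))
    expect_identical(diff(mo) > 0,
                     birch$lambda - birch$a_f * (ep^2 + 0.58^2) > 0)
  }
})

test_that("correlation time inflates the variance and vanishes in the limit", {
  v0 <- formative_moments(1, birch, eta_prime1, 0.58, tau_h = 0)$variance
  for (tau in c(0.5, 2, 10)) {
    mo <- formative_moments(1, birch, eta_prime1, 0.58, tau_h = tau)
    expect_gt(mo$variance, v0)
    expect_gt(mo$V2, 0); expect_gt(mo$V3, 0)
    expect_equal(mo$mean, 0.104804, tolerance = 1e-6)  # mean unaffected
  }
  # variance grows with tau_h at fixed t
  vs <- vapply(c(0.1, 0.5, 2, 10), function(tau) {
    formative_moments(1, birch, eta_prime1, 0.58, tau)$variance
  }, numeric(1))
  expect_true(all(diff(vs) > 0))
  # V2, V3 -> 0 linearly in tau_h: at tau_h = 1e-7 the relative
  # contribution is within 3x of the leading-order value
  # 2*tau + sigma^4*tau/(2*Sigma^2)
  tau <- 1e-7
  mo <- formative_moments(1, birch, eta_prime1, 0.58, tau)
  lead <- 2 * tau + 0.58^4 * tau / (2 * (eta_prime1 * 0.58)^2)
  expect_lt((mo$V2 + mo$V3) / mo$V1, 3 * lead)
  expect_lt((mo$V2 + mo$V3) / mo$V1, 1e-6)
})

test_that("continuity constant matches degenerate and Monte-Carlo oracles", {
  # degenerate limit: variance -> 0 (zero divergence kills Sigma)
  sp <- birch
  c2d <- continuity_constant(sp, 0, 0.58)
  m <- formative_moments(1, sp, 0, 0.58)
  expect_identical(m$variance, 0)
  expect_equal(c2d, log(invlogit(m$mean)))

  # frozen degenerate worked value: mean 0.104804 -> log(0.52620)
  expect_equal(log(invlogit(0.104804)), -0.6421175, tolerance = 1e-6)

  # Monte-Carlo oracle at the plot-1 moments
  c2 <- continuity_constant(sp, eta_prime1, 0.58)
  fm <- formative_moments(1, sp, eta_prime1, 0.58)
  set.seed(77)
  z <- rnorm(2e5, fm$mean, sqrt(fm$variance))
  mc <- log(plogis(z))
  expect_lt(abs(c2 - mean(mc)), 3 * sd(mc) / sqrt(length(mc)))
})

test_that("decline moments are continuous at T_f and match quadrature", {
  c2 <- continuity_constant(birch, eta_prime1, 0.58)
  just <- decline_moments(birch$T_f + 1e-9, birch, eta_prime1, 0.58, c2)
  expect_equal(just$mean, c2, tolerance = 1e-6)
  expect_lt(just$variance, 1e-8)

  flat <- species_params(A = 0.2, B = 0, C = 0, D = 0.04)
  dm <- decline_moments(11, flat, eta_prime1, 0.58, c2 = -0.5)
  M <- eta_prime1^2 + 0.58^2; S2 <- (eta_prime1 * 0.58)^2
  expect_equal(dm$mean, -0.5 - M * 0.2 * 10)
  expect_equal(dm$variance, 4 * S2 * 0.04 * 10)

  # independent quadrature oracle at t = 30 with the calibrated coefficients
  d30 <- decline_moments(30, birch, eta_prime1, 0.58, c2)
  I1 <- integrate(function(s) sensitivity(s, birch), 1, 30,
                  abs.tol = 1e-12, rel.tol = 1e-12)$value
  I2 <- integrate(function(s) sensitivity(s, birch)^2, 1, 30,
                  abs.tol = 1e-13, rel.tol = 1e-13)$value
  expect_equal(d30$mean, c2 - d30$M * I1, tolerance = 1e-8)
  expect_equal(d30$variance, 4 * (eta_prime1 * 0.58)^2 * I2, tolerance = 1e-8)
  expect_error(decline_moments(0.5, birch, eta_prime1, 0.58, c2), "T_f")
})

test_that("abundance PDFs normalize and take their closed forms", {
  fm <- formative_moments(1, birch, eta_prime1, 0.58)
  total <- integrate(function(n) abundance_pdf(n, fm), 0, 1,
                     abs.tol = 1e-10, rel.tol = 1e-10)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_true(all(abundance_pdf(seq(0.01, 0.99, by = 0.01), fm) >= 0))

  # log-normal closed form at n = exp(mean)
  c2 <- continuity_constant(birch, eta_prime1, 0.58)
  dm <- decline_moments(10, birch, eta_prime1, 0.58, c2)
  n0 <- exp(dm$mean)
  expect_equal(abundance_pdf(n0, dm), 1 / (n0 * sqrt(2 * pi * dm$variance)))

  expect_error(abundance_pdf(1.2, fm), "\\(0, 1\\)")
  m0 <- formative_moments(0, birch, eta_prime1, 0.58)
  expect_error(abundance_pdf(0.5, m0), "point mass")
})

test_that("mean abundance peaks at zero divergence", {
  # degenerate variance: mean abundance is invlogit of the mean
  ma0 <- mean_abundance(1, birch, 0, 0.58)
  fm0 <- formative_moments(1, birch, 0, 0.58)
  expect_equal(ma0, invlogit(fm0$mean))

  grid <- seq(-1, 1, by = 0.25)
  ma <- vapply(grid, function(ep) mean_abundance(1, birch, ep, 0.58),
               numeric(1))
  expect_equal(grid[which.max(ma)], 0)
  # symmetric in the divergence sign
  expect_equal(ma[grid == -0.5], ma[grid == 0.5])
})

test_that("moment tables span both stages consistently", {
  tab <- moment_table(birch, eta_prime1, 0.58, times = c(0, 0.5, 1, 5, 30))
  expect_identical(tab$stage, c(rep("formative", 3), rep("decline", 2)))
  expect_identical(tab$transform, c(rep("logit", 3), rep("log", 2)))
  expect_equal(tab$mean[3], 0.104804, tolerance = 1e-6)
  # decline variance non-decreasing in t
  expect_true(all(diff(tab$variance[4:5]) > 0))
})
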