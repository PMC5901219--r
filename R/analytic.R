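#' Stage moments of transformed abundance
#'
#' Internal constructor for the closed-form description of one stage:
#' `transform = "logit"` (formative) or `"log"` (decline), with mean and
#' variance of the transformed abundance plus the substitution variables
#' \eqn{M = \eta'^2 + \sigma^2}, \eqn{\Sigma = \eta'\sigma}, the constants
#' `c1 = logit(epsilon)` and `c2` (decline-stage continuity), and the
#' variance terms `V1`, `V2`, `V3`.
#'
#' @noRd
stage_moments <- function(stage, transform, t, mean, variance,
                          M, Sigma, c1 = NA_real_, c2 = NA_real_,
                          V1 = NA_real_, V2 = NA_real_, V3 = NA_real_) {
  structure(list(stage = stage, transform = transform, t = t,
                 mean = mean, variance = variance, M = M, Sigma = Sigma,
                 c1 = c1, c2 = c2, V1 = V1, V2 = V2, V3 = V3),
            class = "stage_moments")
}

#' @export
print.stage_moments <- function(x, ...) {
  cat(sprintf("%s-stage moments at t = %g yr: %s(n) ~ N(%.6g, %.6g)\n",
              x$stage, x$t, x$transform, x$mean, x$variance))
  invisible(x)
}

#' Formative-stage moments of logit abundance
#'
#' In the formative stage logit(n) is Gaussian with mean
#' \eqn{c_1 + (\lambda - a_f M)t}, \eqn{c_1 = \mathrm{logit}(\epsilon)},
#' \eqn{M = \eta'^2 + \sigma^2}. In the white-noise limit the variance is
#' \eqn{V_1 = 4 a_f^2 \Sigma^2 t} with \eqn{\Sigma = \eta'\sigma}. With a
#' correlation time \eqn{\tau_h > 0} (\eqn{\alpha = 1/\tau_h}) two further
#' terms enter:
#' \deqn{V_2 = \frac{8 a_f^2 \Sigma^2}{\alpha^2}(\alpha t - 1 + e^{-\alpha t}),
#'  \quad V_3 = \frac{a_f^2 \sigma^4}{\alpha^2}(2\alpha t - 1 + e^{-2\alpha t}).}
#' The correlation time inflates the variance but leaves the mean of
#' logit(n) unchanged.
#'
#' @param t age in the formative stage, years; `0 <= t <= T_f`.
#' @param sp a [species_params()].
#' @param eta_prime divergence \eqn{\eta' = \mu - \eta}, metres.
#' @param sigma water-table sd, metres; > 0.
#' @param tau_h correlation time, years; 0 for white noise.
#' @return A `stage_moments` object (transform `"logit"`).
#' @export
formative_moments <- function(t, sp, eta_prime, sigma, tau_h = 0) {
  stopifnot(inherits(sp, "species_params"))
  check_scalar(t, "t", nonneg = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(tau_h, "tau_h", nonneg = TRUE)
  if (t > sp$T_f + 1e-12) stop("formative stage requires t <= T_f", call. = FALSE)
  M <- eta_prime^2 + sigma^2
  Sigma <- eta_prime * sigma
  c1 <- logit(sp$epsilon)
  m <- c1 + (sp$lambda - sp$a_f * M) * t
  V1 <- 4 * sp$a_f^2 * Sigma^2 * t
  if (tau_h > 0) {
    a <- 1 / tau_h
    V2 <- 8 * sp$a_f^2 * Sigma^2 / a^2 * (a * t - 1 + exp(-a * t))
    V3 <- sp$a_f^2 * sigma^4 / a^2 * (2 * a * t - 1 + exp(-2 * a * t))
  } else {
    V2 <- 0
    V3 <- 0
  }
  stage_moments("formative", "logit", t, m, V1 + V2 + V3, M, Sigma,
                c1 = c1, V1 = V1, V2 = V2, V3 = V3)
}

#' Decline-stage moments of log abundance
#'
#' After the formative stage log(n) is a Gaussian diffusion with mean
#' \eqn{m_2(t) = c_2 - M \int_{T_f}^{t} a_d(s)\,ds} (decreasing whenever
#' \eqn{a_d > 0}) and variance \eqn{4\Sigma^2 \int_{T_f}^{t} a_d(s)^2 ds}.
#' The decline stage uses the white-noise treatment: flow fluctuates
#' orders of magnitude faster than a mature population evolves, so
#' correlation-time corrections are negligible there.
#'
#' @param t age, years; must exceed `T_f`.
#' @param sp a [species_params()].
#' @param eta_prime divergence, metres.
#' @param sigma water-table sd, metres.
#' @param c2 continuity constant (mean of log n at `T_f`), from
#'   [continuity_constant()].
#' @return A `stage_moments` object (transform `"log"`).
#' @export
decline_moments <- function(t, sp, eta_prime, sigma, c2) {
  stopifnot(inherits(sp, "species_params"))
  check_scalar(t, "t", positive = TRUE)
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(c2, "c2")
  if (t <= sp$T_f) stop("decline stage requires t > T_f", call. = FALSE)
  M <- eta_prime^2 + sigma^2
  Sigma <- eta_prime * sigma
  m2 <- c2 - M * sensitivity_integral(sp$T_f, t, sp, power = 1)
  v <- 4 * Sigma^2 * sensitivity_integral(sp$T_f, t, sp, power = 2)
  stage_moments("decline", "log", t, m2, v, M, Sigma, c2 = c2)
}

#' Continuity constant between the formative and decline laws
#'
#' The decline-stage law starts from \eqn{c_2 = E[\log n(T_f)]}, computed
#' by adaptive quadrature of \eqn{\log(\mathrm{invlogit}(z))} against the
#' Gaussian law of \eqn{z = \mathrm{logit}\,n(T_f)} (distribution-level
#' continuity; pathwise continuity is enforced in [simulate_cohort()]).
#' Degenerate case: zero formative variance gives
#' \eqn{c_2 = \log(\mathrm{invlogit}(m))}.
#'
#' @inheritParams formative_moments
#' @return The scalar `c2`.
#' @export
continuity_constant <- function(sp, eta_prime, sigma, tau_h = 0) {
  fm <- formative_moments(sp$T_f, sp, eta_prime, sigma, tau_h)
  if (fm$variance == 0) return(log(invlogit(fm$mean)))
  s <- sqrt(fm$variance)
  # integrate on the standardized Gaussian scale to avoid endpoint issues;
  # log(invlogit(x)) evaluated in log space so deep tails do not underflow
  q <- stats::integrate(function(z) stats::plogis(fm$mean + s * z, log.p = TRUE) * dnorm(z),
                        -Inf, Inf, abs.tol = 1e-10, rel.tol = 1e-10,
                        subdivisions = 2000L)
  if (q$abs.error > 1e-6) {
    stop("continuity_constant: quadrature did not converge", call. = FALSE)
  }
  q$value
}

#' Abundance probability density
#'
#' Logit-normal density (formative) or log-normal density (decline) of the
#' normalized abundance implied by the stage moments. The decline-stage
#' log-normal is not truncated to (0, 1]; the mass above 1 is vanishing in
#' the model's regime and is left as the analytic law states it.
#'
#' @param n abundance values in (0, 1), vectorized.
#' @param moments a `stage_moments` object with positive variance.
#' @return Density values (>= 0).
#' @export
abundance_pdf <- function(n, moments) {
  stopifnot(inherits(moments, "stage_moments"))
  if (any(n <= 0 | n >= 1)) stop("`n` must lie in (0, 1)", call. = FALSE)
  if (moments$variance <= 0) {
    stop("zero variance: the law is a point mass, density is not defined",
         call. = FALSE)
  }
  s <- sqrt(moments$variance)
  if (moments$transform == "logit") {
    dnorm(logit(n), moments$mean, s) / (n * (1 - n))
  } else {
    stats::dlnorm(n, meanlog = moments$mean, sdlog = s)
  }
}

#' Mean abundance at a given age
#'
#' \eqn{E[n(t)]} by adaptive quadrature against the stage law: expectation
#' of invlogit (formative) or exp (decline) of the Gaussian transformed
#' abundance, integrated on the standardized Gaussian scale.
#'
#' @inheritParams formative_moments
#' @param t age, years.
#' @return Expected abundance.
#' @export
mean_abundance <- function(t, sp, eta_prime, sigma, tau_h = 0) {
  stopifnot(inherits(sp, "species_params"))
  if (t <= sp$T_f) {
    fm <- formative_moments(t, sp, eta_prime, sigma, tau_h)
    if (fm$variance == 0) return(invlogit(fm$mean))
    s <- sqrt(fm$variance)
    stats::integrate(function(z) invlogit(fm$mean + s * z) * dnorm(z),
                     -Inf, Inf, abs.tol = 1e-10, rel.tol = 1e-10,
                     subdivisions = 2000L)$value
  } else {
    c2 <- continuity_constant(sp, eta_prime, sigma, tau_h)
    dm <- decline_moments(t, sp, eta_prime, sigma, c2)
    if (dm$variance == 0) return(exp(dm$mean))
    s <- sqrt(dm$variance)
    stats::integrate(function(z) exp(dm$mean + s * z) * dnorm(z),
                     -Inf, Inf, abs.tol = 1e-10, rel.tol = 1e-10,
                     subdivisions = 2000L)$value
  }
}

#' Tabulate stage moments over an age grid
#'
#' Convenience wrapper producing a long table of (t, stage, mean,
#' variance) spanning both stages, used by the `analytic` workflow.
#'
#' @param sp a [species_params()].
#' @param eta_prime divergence, metres.
#' @param sigma water-table sd, metres.
#' @param tau_h correlation time, years.
#' @param times ages, years (values <= `T_f` use the formative law).
#' @return A data.frame with columns `t`, `stage`, `transform`, `mean`,
#'   `variance`.
#' @export
moment_table <- function(sp, eta_prime, sigma, tau_h = 0,
                         times = seq(0, sp$t_maxage, by = 0.5)) {
  c2 <- continuity_constant(sp, eta_prime, sigma, tau_h)
  rows <- lapply(times, function(t) {
    mo <- if (t <= sp$T_f) {
      formative_moments(t, sp, eta_prime, sigma, tau_h)
    } else {
      decline_moments(t, sp, eta_prime, sigma, c2)
    }
    data.frame(t = t, stage = mo$stage, transform = mo$transform,
               mean = mo$mean, variance = mo$variance)
  })
  do.call(rbind, rows)
}
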