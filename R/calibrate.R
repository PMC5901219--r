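#' Formative-stage logit-slopes per plot
#'
#' In the formative stage the mean of logit(n) is linear in age with slope
#' \eqn{v_i = \lambda - a_f M_i}; the slope is estimated per plot by
#' ordinary least squares of logit(abundance) on time.
#'
#' @param samples data.frame with columns `plot_id`, `time`, `abundance`
#'   (abundance in (0,1)); all times within the formative stage, at least
#'   two distinct times per plot.
#' @return A data.frame with columns `plot_id`, `slope`, `intercept`,
#'   `n_samples`.
#' @export
fit_plot_slopes <- function(samples) {
  req <- c("plot_id", "time", "abundance")
  if (!all(req %in% names(samples))) {
    stop("samples needs columns plot_id, time, abundance", call. = FALSE)
  }
  if (any(samples$abundance <= 0 | samples$abundance >= 1)) {
    stop("abundance values must lie in (0, 1)", call. = FALSE)
  }
  out <- lapply(split(samples, samples$plot_id), function(d) {
    if (length(unique(d$time)) < 2L) {
      stop("plot ", d$plot_id[1], ": need at least 2 distinct time points",
           call. = FALSE)
    }
    fit <- stats::lm(logit(abundance) ~ time, data = d)
    data.frame(plot_id = d$plot_id[1],
               slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               n_samples = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Solve the multi-plot calibration system for species parameters
#'
#' Given formative-stage slopes \eqn{v_i} from at least three plots at
#' distinct altitudes and a fitted flow regime, solves
#' \deqn{\lambda - a_f(\eta_i'^2 + \sigma^2) = v_i, \qquad
#'   \eta_i' = \eta_1' - (\mathrm{alt}_i - \mathrm{alt}_1),}
#' for \eqn{(\lambda, a_f, \eta_1')} by bounded nonlinear least squares
#' (Levenberg-Marquardt) with multi-start over a coarse \eqn{\eta_1'}
#' grid — the quadratic system is non-convex and, when all plots sit on
#' one side of \eqn{\eta' = 0}, has a mirrored local optimum, which is
#' reported as `alternative`. The favorable-level differences between
#' plots equal their altitude differences by construction.
#'
#' @param slopes data.frame from [fit_plot_slopes()] (or with columns
#'   `plot_id`, `slope`).
#' @param plots data.frame with columns `plot_id`, `altitude` (m; distinct),
#'   optionally `distance`.
#' @param regime a [flow_regime()]; supplies `sigma` and `mu`.
#' @return An object of class `calibration_result`: list with `lambda`,
#'   `a_f`, `eta_prime` (per plot), `eta` (per plot, `mu - eta_prime`),
#'   `v` (slopes), `residual_norm`, `alternative` (second-best distinct
#'   local optimum or NULL).
#' @export
solve_species_params <- function(slopes, plots, regime) {
  stopifnot(inherits(regime, "flow_regime"))
  if (!all(c("plot_id", "slope") %in% names(slopes))) {
    stop("slopes needs columns plot_id, slope", call. = FALSE)
  }
  if (!all(c("plot_id", "altitude") %in% names(plots))) {
    stop("plots needs columns plot_id, altitude", call. = FALSE)
  }
  d <- merge(plots, slopes, by = "plot_id", sort = TRUE)
  if (nrow(d) < 3L) stop("need at least 3 plots", call. = FALSE)
  if (anyDuplicated(d$altitude)) {
    stop("plot altitudes must be distinct (system rank-deficient)", call. = FALSE)
  }
  d <- d[order(d$altitude), ]
  dalt <- d$altitude - d$altitude[1]
  v <- d$slope
  sig <- regime$sigma

  res_fn <- function(p) {
    v - (p[1] - p[2] * ((p[3] - dalt)^2 + sig^2))
  }
  starts <- expand.grid(lambda = max(v) + c(0.5, 2),
                        a_f = c(0.1, 0.5, 2),
                        ep1 = seq(-3, 3, by = 1))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = res_fn,
                         lower = c(1e-8, 1e-8, -Inf),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("calibration failed to converge from any start", call. = FALSE)
  norms <- vapply(fits, function(f) sqrt(sum(res_fn(f$par)^2)), numeric(1))
  ord <- order(norms)
  best <- fits[[ord[1]]]
  p <- best$par

  # second-best distinct optimum (mirror candidate)
  alt_sol <- NULL
  for (j in ord[-1]) {
    q <- fits[[j]]$par
    if (abs(q[3] - p[3]) > 1e-3 && norms[j] < norms[ord[1]] + 1e-3 * max(1, norms[ord[1]])) {
      alt_sol <- list(lambda = q[1], a_f = q[2], eta_prime1 = q[3],
                      residual_norm = norms[j])
      break
    }
  }

  eta_prime <- p[3] - dalt
  structure(list(lambda = p[1], a_f = p[2],
                 plot_id = d$plot_id,
                 eta_prime = eta_prime,
                 eta = regime$mu - eta_prime,
                 v = v,
                 residual_norm = norms[ord[1]],
                 alternative = alt_sol),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration result: lambda =", signif(x$lambda, 6),
      "yr^-1, a_f =", signif(x$a_f, 6), "yr^-1 m^-2\n")
  print(data.frame(plot_id = x$plot_id, eta = signif(x$eta, 6),
                   eta_prime = signif(x$eta_prime, 6), slope = x$v))
  cat("residual norm:", format(x$residual_norm, digits = 4), "\n")
  if (!is.null(x$alternative)) {
    cat("note: mirrored alternative solution with eta_prime[1] =",
        signif(x$alternative$eta_prime1, 6), "\n")
  }
  invisible(x)
}

#' Synthetic formative-stage samples for calibration tests
#'
#' Draws per-plot abundance samples from the analytic formative law:
#' logit(n) at each time is Gaussian with mean
#' \eqn{c_1 + (\lambda - a_f M_i)t} and variance \eqn{V_1(t)}, plus
#' optional extra observation noise on the logit scale. `noise_sd = 0`
#' suppresses both and returns exactly logit-linear-in-mean samples.
#'
#' @param sp a [species_params()] (the true parameters).
#' @param plots data.frame with columns `plot_id`, `eta` (favorable level,
#'   m), optionally `altitude`, `distance`.
#' @param regime a [flow_regime()].
#' @param noise_sd extra observation noise sd on the logit scale (0 for a
#'   noiseless fixture; the process noise V1 is also suppressed then).
#' @param n_times sample times per plot, evenly spaced over (0, `T_f`].
#' @param seed integer seed.
#' @return A data.frame with columns `plot_id`, `time`, `abundance`.
#' @export
generate_calibration_fixture <- function(sp, plots, regime, noise_sd = 0,
                                         n_times = 5L, seed = 1L) {
  stopifnot(inherits(sp, "species_params"), inherits(regime, "flow_regime"))
  if (!all(c("plot_id", "eta") %in% names(plots))) {
    stop("plots needs columns plot_id, eta", call. = FALSE)
  }
  times <- seq(sp$T_f / n_times, sp$T_f, length.out = n_times)
  with_seed(sub_seed(seed, "fixture"), {
    rows <- lapply(seq_len(nrow(plots)), function(i) {
      ep <- regime$mu - plots$eta[i]
      m <- vapply(times, function(t) {
        formative_moments(t, sp, ep, regime$sigma)$mean
      }, numeric(1))
      if (noise_sd > 0) {
        v1 <- vapply(times, function(t) {
          formative_moments(t, sp, ep, regime$sigma)$variance
        }, numeric(1))
        z <- m + sqrt(v1) * rnorm(length(times)) + noise_sd * rnorm(length(times))
      } else {
        z <- m
      }
      data.frame(plot_id = plots$plot_id[i], time = times,
                 abundance = invlogit(z))
    })
    do.call(rbind, rows)
  })
}
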