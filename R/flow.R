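#' Stationary flood water-table regime
#'
#' A flow regime is the stationary Gaussian description of the flood water
#' table: mean level \eqn{\mu} (m), standard deviation \eqn{\sigma} (m) and
#' correlation time \eqn{\tau_h} (years). `tau_h = 0` encodes the
#' white-Gaussian-noise limit (flow fluctuating much faster than the
#' vegetation); `tau_h > 0` an Ornstein-Uhlenbeck process with reversion
#' rate \eqn{\alpha = 1/\tau_h}.
#'
#' @param mu mean water level, metres.
#' @param sigma standard deviation of the water level, metres; must be > 0.
#' @param tau_h correlation time, years; `0` for the white-noise limit.
#' @return An object of class `flow_regime`.
#' @examples
#' flow_regime(mu = 82.8, sigma = 0.58, tau_h = 0)
#' @export
flow_regime <- function(mu, sigma, tau_h = 0) {
  check_scalar(mu, "mu")
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(tau_h, "tau_h", nonneg = TRUE)
  structure(
    list(mu = mu, sigma = sigma, tau_h = tau_h,
         alpha = if (tau_h > 0) 1 / tau_h else NA_real_),
    class = "flow_regime"
  )
}

#' @export
print.flow_regime <- function(x, ...) {
  cat("Flow regime: mu =", x$mu, "m, sigma =", x$sigma, "m, tau_h =",
      x$tau_h, "yr", if (x$tau_h == 0) "(white-noise limit)" else "(O-U)", "\n")
  invisible(x)
}

#' Piecewise-stationary (segmented) flow regime
#'
#' A nonstationary flow record is approximated by consecutive stationary
#' segments, each with its own regime. Segments must be contiguous,
#' non-overlapping and ordered.
#'
#' @param t_start,t_end numeric vectors of segment boundaries, years.
#' @param regimes list of [flow_regime()] objects, one per segment.
#' @return An object of class `segmented_regime`.
#' @export
segmented_regime <- function(t_start, t_end, regimes) {
  if (length(t_start) != length(t_end) || length(t_start) != length(regimes)) {
    stop("t_start, t_end and regimes must have equal length", call. = FALSE)
  }
  if (any(t_start >= t_end)) stop("each segment needs t_start < t_end", call. = FALSE)
  if (length(t_start) > 1L &&
      max(abs(t_start[-1] - t_end[-length(t_end)])) > 1e-9) {
    stop("segments must be contiguous and non-overlapping", call. = FALSE)
  }
  ok <- vapply(regimes, inherits, logical(1), what = "flow_regime")
  if (!all(ok)) stop("all regimes must be flow_regime objects", call. = FALSE)
  structure(list(t_start = t_start, t_end = t_end, regimes = regimes),
            class = "segmented_regime")
}

#' @export
print.segmented_regime <- function(x, ...) {
  cat("Segmented flow regime with", length(x$regimes), "segments over [",
      x$t_start[1], ",", x$t_end[length(x$t_end)], "] yr\n")
  invisible(x)
}

# Regime in force at time t (right-open segments; last segment closed).
regime_at <- function(seg, t) {
  if (inherits(seg, "flow_regime")) return(seg)
  k <- findInterval(t, seg$t_start)
  k <- min(max(k, 1L), length(seg$regimes))
  if (t > seg$t_end[length(seg$t_end)] + 1e-9 || t < seg$t_start[1] - 1e-9) {
    stop("time ", t, " outside the segmented regime's coverage", call. = FALSE)
  }
  seg$regimes[[k]]
}

#' Uniformly sampled water-level series
#'
#' @param times uniformly spaced times, years.
#' @param levels water levels, metres.
#' @return An object of class `flow_series` (also a data.frame with columns
#'   `time` and `level`).
#' @export
flow_series <- function(times, levels) {
  if (length(times) != length(levels)) stop("times and levels must match", call. = FALSE)
  check_uniform_grid(times)
  structure(data.frame(time = times, level = levels),
            class = c("flow_series", "data.frame"))
}

#' Sample a water-table path from a stationary regime
#'
#' For `tau_h > 0` uses the exact stationary Ornstein-Uhlenbeck transition
#' \deqn{h_{k+1} = \mu + (h_k-\mu)e^{-\alpha\Delta} +
#'   \sigma\sqrt{1-e^{-2\alpha\Delta}}\,Z_k,}
#' with \eqn{h_0} drawn from the stationary law \eqn{N(\mu,\sigma^2)}.
#' For `tau_h = 0` the levels are i.i.d. Gaussian draws per grid point — a
#' discrete visualisation/estimation stand-in for the white-noise limit
#' (white noise proper is handled analytically elsewhere, never sampled as
#' a continuous-time object).
#'
#' @param regime a [flow_regime()].
#' @param tgrid uniform time grid, years, at least 2 points.
#' @param seed integer seed; identical inputs give identical output.
#' @return A [flow_series()].
#' @export
sample_water_table <- function(regime, tgrid, seed) {
  stopifnot(inherits(regime, "flow_regime"))
  dt <- check_uniform_grid(tgrid)
  n <- length(tgrid)
  h <- with_seed(seed, {
    if (regime$tau_h > 0) {
      a <- regime$alpha
      rho <- exp(-a * dt)
      innov_sd <- regime$sigma * sqrt(1 - rho^2)
      z <- rnorm(n)
      out <- numeric(n)
      out[1] <- regime$mu + regime$sigma * z[1]
      for (k in seq_len(n - 1L)) {
        out[k + 1L] <- regime$mu + (out[k] - regime$mu) * rho + innov_sd * z[k + 1L]
      }
      out
    } else {
      rnorm(n, regime$mu, regime$sigma)
    }
  })
  flow_series(tgrid, h)
}

#' Estimate a flow regime from a level series
#'
#' Mean and sd are the sample moments. The correlation time is estimated by
#' a log-linear least-squares fit of \eqn{\exp(-\mathrm{lag}/\tau)} to the
#' empirical autocorrelation over the positive-autocorrelation lags up to
#' `max_lag`; if the lag-1 autocorrelation is not positive, `tau_h` is
#' clamped to 0 (white-noise limit).
#'
#' @param series a [flow_series()] with at least `min_points` points.
#' @param max_lag maximum lag (in steps) used in the autocorrelation fit.
#' @param min_points minimum series length required.
#' @return A [flow_regime()] with estimated parameters.
#' @export
estimate_regime <- function(series, max_lag = 50L, min_points = 50L) {
  stopifnot(inherits(series, "flow_series"))
  if (nrow(series) < min_points) {
    stop("need at least ", min_points, " points to estimate a regime", call. = FALSE)
  }
  x <- series$level
  if (stats::sd(x) == 0) stop("constant series: variance is zero", call. = FALSE)
  dt <- series$time[2] - series$time[1]
  mu_hat <- mean(x)
  sd_hat <- stats::sd(x)
  r <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  if (r[1] <= 0) {
    tau_hat <- 0
  } else {
    # positive run of the ACF up to the first non-positive value
    last <- which(r <= 0)
    upto <- if (length(last)) last[1] - 1L else length(r)
    lags <- dt * seq_len(upto)
    # log rho_k = -lag_k / tau  (regression through the origin)
    slope <- sum(lags * log(r[seq_len(upto)])) / sum(lags^2)
    tau_hat <- if (slope < 0) -1 / slope else 0
  }
  flow_regime(mu = mu_hat, sigma = sd_hat, tau_h = tau_hat)
}

#' Gaussianity check for water-level records
#'
#' Applies the Anderson-Darling omnibus normality test to the level values
#' (chosen as a single standard test that remains valid at the series
#' lengths typical of hydrometric records).
#'
#' @param series a [flow_series()] with at least 20 points.
#' @return A list with `statistic`, `p_value` and `method`.
#' @export
gaussian_fit_test <- function(series) {
  stopifnot(inherits(series, "flow_series"))
  if (nrow(series) < 20L) stop("need at least 20 points", call. = FALSE)
  if (stats::sd(series$level) == 0) stop("constant series: variance is zero", call. = FALSE)
  ht <- nortest::ad.test(series$level)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "Anderson-Darling")
}

#' Piecewise-stationary approximation of a sine-like regime drift
#'
#' Builds a [segmented_regime()] whose segment means and standard
#' deviations trace one sinusoidal drift, evaluated at segment midpoints:
#' \eqn{\mu_k = \mu + A_\mu \sin(2\pi t_k/P)} and analogously for
#' \eqn{\sigma_k}. Midpoint evaluation keeps each segment's value an
#' unbiased within-segment representative.
#'
#' @param base a [flow_regime()] giving the undrifted \eqn{\mu,\sigma,\tau_h}.
#' @param mean_amplitude amplitude of the mean-level drift, metres.
#' @param sd_amplitude amplitude of the sd drift, metres; must be < `base$sigma`.
#' @param period drift period, years.
#' @param horizon total coverage, years.
#' @param n_segments number of equal-width segments (>= 1).
#' @return A [segmented_regime()] covering `[0, horizon]`.
#' @export
make_drifting_regime <- function(base, mean_amplitude, sd_amplitude, period,
                                 horizon, n_segments) {
  stopifnot(inherits(base, "flow_regime"))
  check_scalar(mean_amplitude, "mean_amplitude")
  check_scalar(sd_amplitude, "sd_amplitude", nonneg = TRUE)
  check_scalar(period, "period", positive = TRUE)
  check_scalar(horizon, "horizon", positive = TRUE)
  if (n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  if (sd_amplitude >= base$sigma) {
    stop("sd_amplitude must be < base sigma (sigma_k must stay > 0)", call. = FALSE)
  }
  w <- horizon / n_segments
  t0 <- (seq_len(n_segments) - 1) * w
  tm <- t0 + w / 2
  regs <- lapply(seq_len(n_segments), function(k) {
    flow_regime(
      mu = base$mu + mean_amplitude * sin(2 * pi * tm[k] / period),
      sigma = base$sigma + sd_amplitude * sin(2 * pi * tm[k] / period),
      tau_h = base$tau_h
    )
  })
  segmented_regime(t0, t0 + w, regs)
}

#' Read / write water-level series as delimited text
#'
#' Two-column CSV with header `time,level` (years, metres); lines starting
#' with `#` hold metadata and are skipped on read.
#'
#' @param path file path.
#' @param series a [flow_series()].
#' @param meta optional named list written as `# key: value` header lines.
#' @return `read_flow_series()` returns a [flow_series()].
#' @export
read_flow_series <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "level") %in% names(df))) {
    stop("expected columns `time` and `level`", call. = FALSE)
  }
  flow_series(df$time, df$level)
}

#' @rdname read_flow_series
#' @export
write_flow_series <- function(series, path, meta = NULL) {
  stopifnot(inherits(series, "flow_series"))
  write_table_with_meta(as.data.frame(series), path, meta)
  invisible(path)
}
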