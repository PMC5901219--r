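#' Monte-Carlo simulation of cohort abundance
#'
#' Integrates the stochastic cohort dynamics under Stratonovich calculus in
#' transformed space, where the noise is additive (so the Ito and
#' Stratonovich readings coincide and no Milstein-type correction is
#' needed). Two modes:
#'
#' * `"wgn_exact"` (white-noise forcing, `tau_h = 0`): the exact
#'   transformed-space update
#'   \deqn{\mathrm{logit}\,n_{k+1} = \mathrm{logit}\,n_k +
#'     (\lambda - a_f M)\Delta + 2 a_f |\Sigma| \sqrt{\Delta} Z_k}
#'   in the formative stage, and
#'   \deqn{\log n_{k+1} = \log n_k - a_d(t_k) M \Delta +
#'     2 |\Sigma\, a_d(t_k)| \sqrt{\Delta} Z_k}
#'   in the decline stage (sensitivity frozen per step).
#' * `"ou_pathwise"` (`tau_h > 0`): samples a literal Ornstein-Uhlenbeck
#'   water-table path and integrates the random ODE
#'   \eqn{d\,\mathrm{logit}(n)/dt = \lambda - a_f (h-\eta)^2} (formative) /
#'   \eqn{d\log n/dt = -a_d(t)(h-\eta)^2} (decline) with Heun's
#'   second-order scheme. This is the formula-free reference for the
#'   colored-noise variance terms.
#'
#' Paths switch stage pathwise at `T_f` (log n continues from
#' log(invlogit) of the formative state). Segmented regimes switch
#' \eqn{(\mu,\sigma,\tau_h)} at segment boundaries with the divergence
#' recomputed per segment; in O-U mode the absolute level is kept
#' continuous across boundaries. Abundance is kept in (0, 1]: the
#' transformed state is floored at log(1e-300) and the decline-stage log
#' abundance capped at 0.
#'
#' @param sp a [species_params()].
#' @param regime a [flow_regime()] or [segmented_regime()].
#' @param eta favorable water level of the plot, metres.
#' @param t_end simulation horizon, years (grid starts at 0 with
#'   `n(0) = epsilon`).
#' @param dt time step, years; must satisfy
#'   `dt <= 0.01 * min(1, tau_h)` (`tau_h` taken as 1 in the white-noise
#'   case) and divide both `T_f` and `record_dt`.
#' @param n_paths number of Monte-Carlo paths.
#' @param seed integer seed (byte-identical ensembles for identical inputs).
#' @param mode `"wgn_exact"` or `"ou_pathwise"`.
#' @param record_dt spacing of stored time points, years (a multiple of
#'   `dt`; defaults to `dt`). Crossing detection in [stopping_times()]
#'   works at this stored resolution.
#' @return An object of class `cohort_ensemble`: list with `time` (stored
#'   grid), `n` (matrix, time x paths), `seed`, `mode` and `params`.
#' @export
simulate_cohort <- function(sp, regime, eta, t_end, dt = 0.01,
                            n_paths = 100L, seed = 1L,
                            mode = c("wgn_exact", "ou_pathwise"),
                            record_dt = dt) {
  stopifnot(inherits(sp, "species_params"))
  mode <- match.arg(mode)
  check_scalar(eta, "eta")
  check_scalar(t_end, "t_end", positive = TRUE)
  check_scalar(dt, "dt", positive = TRUE)
  regs <- if (inherits(regime, "segmented_regime")) regime$regimes else list(regime)
  taus <- vapply(regs, function(r) r$tau_h, numeric(1))
  dt_max <- 0.01 * min(1, ifelse(taus > 0, taus, 1))
  if (dt > dt_max + 1e-12) {
    stop("dt = ", dt, " too coarse: need dt <= ", dt_max, call. = FALSE)
  }
  if (mode == "ou_pathwise" && any(taus == 0)) {
    stop("ou_pathwise mode requires tau_h > 0", call. = FALSE)
  }
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-9) {
    stop("t_end must be a multiple of dt", call. = FALSE)
  }
  kf <- round(sp$T_f / dt)
  if (abs(kf * dt - sp$T_f) > 1e-9) {
    stop("T_f must be a multiple of dt", call. = FALSE)
  }
  thin <- round(record_dt / dt)
  if (abs(thin * dt - record_dt) > 1e-9 || thin < 1) {
    stop("record_dt must be a positive multiple of dt", call. = FALSE)
  }
  rec_idx <- seq(0L, n_steps, by = thin)
  times <- rec_idx * dt
  nmat <- matrix(NA_real_, nrow = length(rec_idx), ncol = n_paths)

  FLOOR <- log(1e-300)
  with_seed(seed, {
    y <- rep(logit(sp$epsilon), n_paths)   # transformed state
    stage_log <- FALSE                      # FALSE: logit scale; TRUE: log scale
    nmat[1L, ] <- rep(sp$epsilon, n_paths)
    row <- 1L
    if (mode == "ou_pathwise") {
      r0 <- regime_at(regime, 0)
      h <- r0$mu + r0$sigma * rnorm(n_paths)  # stationary initial level
    }
    for (k in seq_len(n_steps)) {
      t0 <- (k - 1L) * dt
      t1 <- k * dt
      r <- regime_at(regime, t0)
      if (mode == "wgn_exact") {
        eta_p <- r$mu - eta
        M <- eta_p^2 + r$sigma^2
        S <- abs(eta_p * r$sigma)
        z <- rnorm(n_paths)
        if (!stage_log) {
          y <- y + (sp$lambda - sp$a_f * M) * dt + 2 * sp$a_f * S * sqrt(dt) * z
        } else {
          ad <- sensitivity(t0, sp)
          y <- y - ad * M * dt + 2 * S * abs(ad) * sqrt(dt) * z
          y <- pmin(y, 0)
        }
      } else {
        r1 <- regime_at(regime, min(t1, t0 + dt))
        rho <- exp(-dt / r$tau_h)
        h_new <- r$mu + (h - r$mu) * rho +
          r$sigma * sqrt(1 - rho^2) * rnorm(n_paths)
        if (!stage_log) {
          f0 <- sp$lambda - sp$a_f * (h - eta)^2
          f1 <- sp$lambda - sp$a_f * (h_new - eta)^2
          y <- y + dt / 2 * (f0 + f1)
        } else {
          f0 <- -sensitivity(t0, sp) * (h - eta)^2
          f1 <- -sensitivity(t1, sp) * (h_new - eta)^2
          y <- y + dt / 2 * (f0 + f1)
          y <- pmin(y, 0)
        }
        h <- h_new
      }
      y <- pmax(y, FLOOR)
      if (k == kf && !stage_log) {   # pathwise stage hand-over at T_f
        y <- pmin(log(invlogit(y)), 0)
        stage_log <- TRUE
      }
      if (k %% thin == 0L) {
        row <- row + 1L
        nmat[row, ] <- if (stage_log) exp(y) else invlogit(y)
      }
    }
  })

  structure(list(time = times, n = nmat, seed = as.integer(seed), mode = mode,
                 params = list(sp = sp, regime = regime, eta = eta,
                               t_end = t_end, dt = dt, record_dt = record_dt,
                               n_paths = n_paths)),
            class = "cohort_ensemble")
}

#' @export
print.cohort_ensemble <- function(x, ...) {
  cat("Cohort ensemble (", x$mode, "): ", ncol(x$n), " paths over [0, ",
      max(x$time), "] yr, ", length(x$time), " stored points, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

#' First-passage (extinction) times of ensemble paths
#'
#' Per path, the first stored time `t > 0` at which abundance falls below
#' the extinction threshold `n_e`; paths that never cross are censored at
#' the horizon. Detection is at the stored-grid resolution (no
#' Brownian-bridge correction); its bias is controlled by `record_dt`.
#'
#' @param ens a `cohort_ensemble`.
#' @param n_e extinction threshold; must be below the initial abundance.
#' @return A data.frame with columns `path`, `time`, `censored`.
#' @export
stopping_times <- function(ens, n_e) {
  stopifnot(inherits(ens, "cohort_ensemble"))
  check_scalar(n_e, "n_e", nonneg = TRUE)
  if (n_e >= ens$params$sp$epsilon) {
    stop("n_e must be below the initial abundance epsilon", call. = FALSE)
  }
  horizon <- max(ens$time)
  live <- ens$time > 0
  idx <- apply(ens$n[live, , drop = FALSE] < n_e, 2L, function(col) {
    w <- which(col)
    if (length(w)) w[1] else NA_integer_
  })
  tms <- ens$time[live][idx]
  censored <- is.na(idx)
  tms[censored] <- horizon
  data.frame(path = seq_len(ncol(ens$n)), time = tms, censored = censored)
}

#' Long-format ensemble table
#'
#' Columnar (path, time, n) representation of an ensemble for persistence
#' via [write_table_with_meta()]; the metadata header should carry the
#' ensemble's parameters, seed and mode.
#'
#' @param ens a `cohort_ensemble`.
#' @return A data.frame with columns `path`, `time`, `n`.
#' @export
ensemble_table <- function(ens) {
  stopifnot(inherits(ens, "cohort_ensemble"))
  data.frame(path = rep(seq_len(ncol(ens$n)), each = nrow(ens$n)),
             time = rep(ens$time, ncol(ens$n)),
             n = as.vector(ens$n))
}

#' Ensemble summary table
#'
#' Mean and variance of abundance (and of the stage-appropriate transform)
#' at each stored time.
#'
#' @param ens a `cohort_ensemble`.
#' @return A data.frame with columns `t`, `mean_n`, `var_n`.
#' @export
ensemble_summary <- function(ens) {
  stopifnot(inherits(ens, "cohort_ensemble"))
  data.frame(t = ens$time,
             mean_n = rowMeans(ens$n),
             var_n = apply(ens$n, 1L, stats::var))
}
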