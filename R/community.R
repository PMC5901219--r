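#' Multi-cohort age-structure simulation
#'
#' Simulates the full community of same-aged cohorts on one or more plots
#' under a shared (possibly piecewise-stationary) flow regime: every year
#' one new cohort germinates at abundance `epsilon` per plot, each cohort
#' advances on its own age clock (formative for age <= `T_f`, then decline
#' with `a_d(age)`), and a cohort is removed once its abundance falls
#' below `n_e` (recorded as 0 afterwards). Cohort dynamics use the exact
#' white-noise transformed-space update with `paths_per_cohort`
#' Monte-Carlo paths per cohort, reported as the ensemble mean
#' (`paths_per_cohort = 1` gives a single stochastic realization).
#' Cohorts within a plot see the same regime; per-plot noise streams are
#' derived from the seed and the plot's favorable level, so plots with
#' identical `eta` and a shared seed produce identical records while
#' plots with distinct `eta` draw independently.
#'
#' Totals are plain sums over living cohorts — there is no inter-cohort
#' competition or shared carrying capacity — so total abundance is in
#' "cohort units" and may exceed 1.
#'
#' @param sp a [species_params()].
#' @param plots data.frame with columns `plot_id`, `eta` (favorable level,
#'   metres).
#' @param regime a [flow_regime()] or [segmented_regime()] covering
#'   `[0, years]`; the community simulation uses the white-noise
#'   treatment, so all segments must have `tau_h = 0`.
#' @param years simulated horizon, whole years > 0.
#' @param seed integer seed.
#' @param paths_per_cohort Monte-Carlo paths per cohort (default 100 for
#'   smooth output).
#' @param dt integration step, years; must divide 1 and `T_f`.
#' @param n_germination_years recruitment window: new cohorts germinate
#'   only in the first `n_germination_years` years (default: every year).
#' @return An object of class `age_structure_record`: list with `record`
#'   (data.frame: `plot_id`, `year`, `cohort_birth_year`, `age`,
#'   `abundance`), `totals` (data.frame: `plot_id`, `year`, `total`),
#'   `regime_trace` (data.frame: `year`, `mu`, `sigma`), and `params`.
#' @export
simulate_community <- function(sp, plots, regime, years, seed = 1L,
                               paths_per_cohort = 100L, dt = 0.01,
                               n_germination_years = years) {
  stopifnot(inherits(sp, "species_params"))
  if (!all(c("plot_id", "eta") %in% names(plots))) {
    stop("plots needs columns plot_id, eta", call. = FALSE)
  }
  if (!is.numeric(years) || years <= 0 || years != round(years)) {
    stop("years must be a positive whole number", call. = FALSE)
  }
  regs <- if (inherits(regime, "segmented_regime")) regime$regimes else list(regime)
  if (any(vapply(regs, function(r) r$tau_h, numeric(1)) > 0)) {
    stop("simulate_community uses the white-noise treatment: all regime ",
         "segments must have tau_h = 0", call. = FALSE)
  }
  if (inherits(regime, "segmented_regime") &&
      (regime$t_start[1] > 1e-9 || regime$t_end[length(regime$t_end)] < years - 1e-9)) {
    stop("segmented regime must cover [0, years]", call. = FALSE)
  }
  steps <- round(1 / dt)
  if (abs(steps * dt - 1) > 1e-9) stop("dt must divide 1 year", call. = FALSE)
  if (abs(round(sp$T_f / dt) * dt - sp$T_f) > 1e-9) {
    stop("T_f must be a multiple of dt", call. = FALSE)
  }
  FLOOR <- log(1e-300)

  rec <- list()
  tot <- list()
  for (ip in seq_len(nrow(plots))) {
    eta <- plots$eta[ip]
    pid <- plots$plot_id[ip]
    plot_rows <- list()
    with_seed(sub_seed(seed, paste0("plot-", format(eta, digits = 12))), {
      cohorts <- list()   # each: birth, y (transformed), stage_log, alive
      for (yr in seq_len(years)) {
        # new cohort germinates at the start of year `yr` (birth year yr - 1)
        if (yr <= n_germination_years) {
          cohorts[[length(cohorts) + 1L]] <- list(
            birth = yr - 1L,
            y = rep(logit(sp$epsilon), paths_per_cohort),
            stage_log = FALSE, alive = TRUE)
        }
        for (ci in seq_along(cohorts)) {
          co <- cohorts[[ci]]
          if (!co$alive) next
          for (k in seq_len(steps)) {
            t_cal <- (yr - 1L) + (k - 1L) * dt
            age0 <- t_cal - co$birth
            r <- regime_at(regime, t_cal)
            eta_p <- r$mu - eta
            M <- eta_p^2 + r$sigma^2
            S <- abs(eta_p * r$sigma)
            z <- rnorm(paths_per_cohort)
            if (!co$stage_log) {
              co$y <- co$y + (sp$lambda - sp$a_f * M) * dt +
                2 * sp$a_f * S * sqrt(dt) * z
            } else {
              ad <- sensitivity(age0, sp)
              co$y <- pmin(co$y - ad * M * dt + 2 * S * abs(ad) * sqrt(dt) * z, 0)
            }
            co$y <- pmax(co$y, FLOOR)
            if (!co$stage_log && abs((age0 + dt) - sp$T_f) < 1e-9) {
              co$y <- pmin(log(invlogit(co$y)), 0)
              co$stage_log <- TRUE
            }
          }
          nbar <- mean(if (co$stage_log) exp(co$y) else invlogit(co$y))
          if (nbar < sp$n_e) {
            co$alive <- FALSE
            nbar <- 0
          }
          cohorts[[ci]] <- co
          plot_rows[[length(plot_rows) + 1L]] <- data.frame(
            plot_id = pid, year = yr, cohort_birth_year = co$birth,
            age = yr - co$birth, abundance = nbar)
        }
      }
    })
    pr <- do.call(rbind, plot_rows)
    rec[[ip]] <- pr
    tt <- tapply(pr$abundance, pr$year, sum)
    tot[[ip]] <- data.frame(plot_id = pid, year = as.integer(names(tt)),
                            total = as.numeric(tt))
  }
  yrs <- seq_len(years)
  trace <- do.call(rbind, lapply(yrs, function(y) {
    r <- regime_at(regime, y - 0.5)
    data.frame(year = y, mu = r$mu, sigma = r$sigma)
  }))
  structure(list(record = do.call(rbind, rec),
                 totals = do.call(rbind, tot),
                 regime_trace = trace,
                 params = list(sp = sp, plots = plots, years = years,
                               seed = as.integer(seed),
                               paths_per_cohort = paths_per_cohort, dt = dt,
                               n_germination_years = n_germination_years)),
            class = "age_structure_record")
}

#' @export
print.age_structure_record <- function(x, ...) {
  cat("Age-structure record:", length(unique(x$record$plot_id)), "plot(s),",
      x$params$years, "years,", x$params$paths_per_cohort,
      "paths per cohort, seed", x$params$seed, "\n")
  invisible(x)
}

#' Age distribution of a plot's abundance in a given year
#'
#' Normalized abundance share by cohort age, with an evenness index (the
#' Shannon entropy of the shares normalized by its maximum, log of the
#' number of living age classes): 1 for equal-abundance cohorts, 0 for a
#' single surviving cohort.
#'
#' @param rec an `age_structure_record`.
#' @param plot_id plot identifier.
#' @param year calendar year within the record.
#' @return A list with `shares` (data.frame: `age`, `abundance`, `share`),
#'   `evenness`, and `empty` (TRUE when the plot has no abundance that
#'   year).
#' @export
age_structure_summary <- function(rec, plot_id, year) {
  stopifnot(inherits(rec, "age_structure_record"))
  d <- rec$record[rec$record$plot_id == plot_id & rec$record$year == year, ]
  if (!nrow(d)) stop("no such plot/year in the record", call. = FALSE)
  d <- d[d$abundance > 0, ]
  total <- sum(d$abundance)
  if (total == 0 || !nrow(d)) {
    return(list(shares = data.frame(age = integer(), abundance = numeric(),
                                    share = numeric()),
                evenness = NA_real_, empty = TRUE))
  }
  shares <- data.frame(age = d$age, abundance = d$abundance,
                       share = d$abundance / total)
  shares <- shares[order(shares$age), ]
  k <- nrow(shares)
  evenness <- if (k == 1L) 0 else {
    -sum(shares$share * log(shares$share)) / log(k)
  }
  list(shares = shares, evenness = evenness, empty = FALSE)
}

#' Lag of total abundance behind the flow-suitability signal
#'
#' Cross-correlates a plot's yearly total abundance with the regime
#' suitability signal \eqn{-(\mu(t)-\eta)^2} and returns the lag (years)
#' at which the correlation peaks; a positive value means abundance lags
#' the flow regime. Both series are linearly detrended first: cohort
#' accumulation puts a trend in the totals that would otherwise swamp the
#' periodic response.
#'
#' @param rec an `age_structure_record`.
#' @param plot_id plot identifier.
#' @param max_lag maximum lag scanned, years.
#' @return A list with `lag` (years) and `correlation` at the peak.
#' @export
abundance_lag <- function(rec, plot_id, max_lag = 15L) {
  stopifnot(inherits(rec, "age_structure_record"))
  tt <- rec$totals[rec$totals$plot_id == plot_id, ]
  if (!nrow(tt)) stop("no such plot in the record", call. = FALSE)
  eta <- rec$params$plots$eta[rec$params$plots$plot_id == plot_id][1]
  suit <- -(rec$regime_trace$mu - eta)^2
  tot <- tt$total[order(tt$year)]
  yrs <- seq_along(tot)
  detrend <- function(v) stats::residuals(stats::lm(v ~ yrs))
  cc <- stats::ccf(detrend(suit), detrend(tot), lag.max = max_lag,
                   plot = FALSE)
  # ccf(x, y) at positive lag k correlates x_{t+k} with y_t; abundance
  # lagging the signal shows up at negative ccf lag, so flip the sign.
  lags <- -as.numeric(cc$lag)
  i <- which.max(as.numeric(cc$acf))
  list(lag = lags[i], correlation = as.numeric(cc$acf)[i])
}
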