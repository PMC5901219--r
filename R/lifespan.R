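#' Mean population lifespan from the stopping-time equation
#'
#' Solves the mean-process crossing equation
#' \deqn{M \int_{T_f}^{\langle T_d\rangle} a_d(t)\,dt = c_2 - \log n_e}
#' for the mean lifespan: the age at which the MEAN of log-abundance
#' reaches the extinction threshold. This is the stopping-theorem
#' definition, not the true mean first-passage time of stochastic paths;
#' [lifespan_mc()] exposes the latter for comparison.
#'
#' The left-hand side uses the closed-form sensitivity integral and the
#' first crossing is located by a sign-change scan plus [stats::uniroot()]
#' (tolerance 1e-12) over `(T_f, 10 t_maxage]`. If the drift never reaches
#' the threshold over that bracket the population is reported as
#' non-extinguishing (`Td = Inf`).
#'
#' @param sp a [species_params()].
#' @param eta_prime divergence, metres.
#' @param sigma water-table sd, metres.
#' @param tau_h formative-stage correlation time, years (enters through
#'   `c2` only; the decline stage uses the white-noise treatment).
#' @param n_e extinction threshold; defaults to `sp$n_e`.
#' @param c2 optionally override the continuity constant (else computed by
#'   [continuity_constant()]).
#' @return A list with `Td` (years, `Inf` if non-extinguishing),
#'   `residual`, `c2`, `M`, `extinguishing`.
#' @export
mean_lifespan <- function(sp, eta_prime, sigma, tau_h = 0,
                          n_e = sp$n_e, c2 = NULL) {
  stopifnot(inherits(sp, "species_params"))
  check_scalar(n_e, "n_e", positive = TRUE)
  if (is.null(c2)) c2 <- continuity_constant(sp, eta_prime, sigma, tau_h)
  M <- eta_prime^2 + sigma^2
  target <- c2 - log(n_e)
  if (target <= 0) {
    stop("population already extinct in mean at T_f (c2 <= log(n_e))",
         call. = FALSE)
  }
  if (M <= 0) {
    return(list(Td = Inf, residual = NA_real_, c2 = c2, M = M,
                extinguishing = FALSE))
  }
  g <- function(T) M * sensitivity_integral(sp$T_f, T, sp, power = 1) - target
  upper <- 10 * sp$t_maxage
  # scan for the first sign change (the drift integral can be non-monotone
  # where a_d dips negative)
  grid <- seq(sp$T_f * (1 + 1e-9), upper, length.out = 400L)
  vals <- vapply(grid, g, numeric(1))
  pos <- which(vals > 0)
  if (!length(pos)) {
    return(list(Td = Inf, residual = NA_real_, c2 = c2, M = M,
                extinguishing = FALSE))
  }
  i <- pos[1]
  lo <- if (i == 1L) sp$T_f * (1 + 1e-9) else grid[i - 1L]
  root <- stats::uniroot(g, lower = lo, upper = grid[i], tol = 1e-12)
  list(Td = root$root, residual = abs(g(root$root)), c2 = c2, M = M,
       extinguishing = TRUE)
}

#' Lifespan as a function of divergence and flow deviation
#'
#' Tabulates the mean lifespan over a grid of divergence values for one or
#' more flow standard deviations, and reports the per-divergence spread
#' across the sigma values. The spread is largest where flow conditions
#' are favorable (small divergence).
#'
#' @param sp a [species_params()].
#' @param eta_prime_grid divergence values, metres.
#' @param sigma_values flow sd values, metres.
#' @param tau_h correlation time, years.
#' @param n_e extinction threshold.
#' @return A list with `table` (data.frame: `eta_prime`, `sigma`, `Td`) and
#'   `spread` (data.frame: `eta_prime`, `spread` = max - min of `Td` over
#'   sigma).
#' @export
lifespan_curve <- function(sp, eta_prime_grid, sigma_values, tau_h = 0,
                           n_e = sp$n_e) {
  if (!length(eta_prime_grid) || !length(sigma_values)) {
    stop("grids must be non-empty", call. = FALSE)
  }
  tab <- expand.grid(eta_prime = eta_prime_grid, sigma = sigma_values,
                     KEEP.OUT.ATTRS = FALSE)
  tab$Td <- mapply(function(e, s) {
    mean_lifespan(sp, e, s, tau_h, n_e = n_e)$Td
  }, tab$eta_prime, tab$sigma)
  spread <- vapply(eta_prime_grid, function(e) {
    td <- tab$Td[tab$eta_prime == e]
    max(td) - min(td)
  }, numeric(1))
  list(table = tab,
       spread = data.frame(eta_prime = eta_prime_grid, spread = spread))
}

#' Monte-Carlo lifespan distribution
#'
#' Simulates an ensemble to a long horizon and summarizes the empirical
#' first-passage (extinction) times, alongside the stopping-time-equation
#' value for comparison. The two need not coincide: the equation tracks
#' the crossing of the mean log-abundance, the Monte-Carlo value the mean
#' of per-path crossings.
#'
#' @inheritParams mean_lifespan
#' @param n_paths Monte-Carlo paths.
#' @param seed integer seed.
#' @param horizon simulation horizon, years (choose well beyond the
#'   expected lifespan; censored paths are reported).
#' @param mu mean water level, metres, used to place the favorable level
#'   (`eta = mu - eta_prime`).
#' @param dt,record_dt integration and storage steps, years.
#' @return A list with `mean`, `quantiles` (5/25/50/75/95%),
#'   `censored_fraction`, `Td_equation`, and the `times` data.frame.
#' @export
lifespan_mc <- function(sp, eta_prime, sigma, tau_h = 0, n_paths = 500L,
                        seed = 1L, horizon = 400, n_e = sp$n_e, mu = 0,
                        dt = 0.01, record_dt = 0.1) {
  regime <- flow_regime(mu = mu, sigma = sigma, tau_h = tau_h)
  mode <- if (tau_h > 0) "ou_pathwise" else "wgn_exact"
  ens <- simulate_cohort(sp, regime, eta = mu - eta_prime, t_end = horizon,
                         dt = dt, n_paths = n_paths, seed = seed,
                         mode = mode, record_dt = record_dt)
  st <- stopping_times(ens, n_e)
  eq <- mean_lifespan(sp, eta_prime, sigma, tau_h, n_e = n_e)
  list(mean = mean(st$time[!st$censored]),
       quantiles = stats::quantile(st$time, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       censored_fraction = mean(st$censored),
       Td_equation = eq$Td,
       times = st)
}
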