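#' Divergence and deviation profiles along a riparian transect
#'
#' With distance `x` from the channel, the saturated water table drops
#' away from the plots' favorable level while soil and the capillary
#' fringe damp its fluctuation. The divergence profile is logarithmic,
#' \eqn{\eta'(x) = \eta'(0) + k \log(1 + x/x_0)}, with the gradient `k`
#' the slow/moderate/rapid knob, and the deviation declines linearly to a
#' floor, \eqn{\sigma(x) = \max(\sigma(0) - s x, \sigma_{min})}.
#'
#' The three stock gradients (`k` = 0.25, 0.35, 0.7 m per log-distance for
#' slow/moderate/rapid with `eta0 = -0.8` m) realize the three qualitative
#' spatial patterns: monotonically increasing, peaked-then-flat, and
#' peaked-then-rapidly-declining.
#'
#' @param kind `"slow"`, `"moderate"` or `"rapid"` (sets `k` unless given).
#' @param x distances from the channel, metres, strictly increasing.
#' @param eta0 divergence at `x = 0`, metres.
#' @param k logarithmic divergence gradient, metres; default by `kind`.
#' @param x0 distance scale of the logarithmic profile, metres.
#' @param sigma0 flow sd at `x = 0`, metres.
#' @param slope linear decline rate of sigma, metres per metre.
#' @param sigma_min sigma floor, metres; > 0.
#' @return An object of class `transect_profile` (data.frame with columns
#'   `x`, `eta_prime`, `sigma`; attribute `kind`).
#' @export
make_profiles <- function(kind = c("slow", "moderate", "rapid"),
                          x = seq(0, 200, by = 2.5),
                          eta0 = -0.8, k = NULL, x0 = 10,
                          sigma0 = 0.58, slope = 0.02, sigma_min = 0.3) {
  kind <- match.arg(kind)
  if (is.null(k)) k <- c(slow = 0.25, moderate = 0.35, rapid = 0.7)[[kind]]
  if (any(diff(x) <= 0)) stop("x must be strictly increasing", call. = FALSE)
  check_scalar(sigma_min, "sigma_min", positive = TRUE)
  ep <- eta0 + k * log(1 + x / x0)
  sg <- pmax(sigma0 - slope * x, sigma_min)
  structure(data.frame(x = x, eta_prime = ep, sigma = sg),
            class = c("transect_profile", "data.frame"),
            kind = kind, k = k)
}

#' Spatial pattern of abundance and lifespan along a transect
#'
#' Evaluates the mean abundance at the end of the formative stage and the
#' mean lifespan pointwise along the transect profile. Both share the same
#' dependence on \eqn{(\eta', \sigma)}: monotone decreasing in \eqn{\sigma}
#' and single-peaked in \eqn{\eta'} with the peak at \eqn{\eta' = 0}.
#'
#' @param profile a [make_profiles()] result.
#' @param sp a [species_params()].
#' @param tau_h correlation time, years.
#' @param t_eval abundance evaluation age, years; must be <= `T_f`.
#' @return A data.frame with columns `x`, `eta_prime`, `sigma`,
#'   `mean_abundance`, `lifespan`.
#' @export
spatial_pattern <- function(profile, sp, tau_h = 0, t_eval = sp$T_f) {
  stopifnot(inherits(profile, "transect_profile"),
            inherits(sp, "species_params"))
  if (t_eval > sp$T_f) {
    stop("t_eval must lie in the formative stage (<= T_f)", call. = FALSE)
  }
  ab <- mapply(function(e, s) mean_abundance(t_eval, sp, e, s, tau_h),
               profile$eta_prime, profile$sigma)
  td <- mapply(function(e, s) mean_lifespan(sp, e, s, tau_h)$Td,
               profile$eta_prime, profile$sigma)
  data.frame(x = profile$x, eta_prime = profile$eta_prime,
             sigma = profile$sigma, mean_abundance = ab, lifespan = td)
}

#' Classify a spatial curve into the three riparian pattern types
#'
#' * `monotonic_increasing`: the curve never falls by more than `rho_tol`
#'   of its range below its running maximum;
#' * otherwise peaked, split by the post-peak drop relative to the rise:
#'   below `theta` gives `peaked_flat`, else `peaked_rapid_decline`.
#'
#' @param values curve values over x (>= 5 points).
#' @param rho_tol monotonicity tolerance as a fraction of the range.
#' @param theta post-peak relative-drop threshold separating flat from
#'   rapidly declining.
#' @return One of `"monotonic_increasing"`, `"peaked_flat"`,
#'   `"peaked_rapid_decline"`.
#' @export
classify_pattern <- function(values, rho_tol = 0.02, theta = 0.3) {
  if (length(values) < 5L) stop("need at least 5 points", call. = FALSE)
  rng <- max(values) - min(values)
  if (rng == 0) return("monotonic_increasing")
  dips <- cummax(values) - values
  if (max(dips) <= rho_tol * rng) return("monotonic_increasing")
  ipk <- which.max(values)
  rise <- values[ipk] - values[1]
  drop <- values[ipk] - min(values[ipk:length(values)])
  if (rise <= 0) return("peaked_rapid_decline")
  if (drop / rise < theta) "peaked_flat" else "peaked_rapid_decline"
}
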