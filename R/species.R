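#' Species-specific model parameters
#'
#' Bundles every species constant of the cohort model: the maximum
#' formative growth rate `lambda` (yr^-1), the formative sensitivity `a_f`
#' (yr^-1 m^-2), the decline-stage sensitivity coefficients `A`, `B`, `C`,
#' `D` of \eqn{a_d(t) = A + B/t + C e^{Dt}}, the formative-stage duration
#' `T_f` (yr), the initial abundance `epsilon` (the small germination
#' abundance), the extinction threshold `n_e`, and optionally the
#' inflection age `t_ip` and maximum age `t_maxage` (yr).
#'
#' The default coefficients are the calibrated white-birch values
#' (`lambda = 3.24`, `a_f = 0.49`, `A = -0.024`, `B = 0.513`,
#' `C = 7e-4`, `D = 0.04`); `T_f = 1` yr is an inferred default, consistent
#' with the continuity constraint \eqn{a_d(T_f) = a_f} since
#' \eqn{a_d(1) = 0.4897 \approx 0.49}.
#'
#' @param lambda maximum formative growth rate, yr^-1; > 0.
#' @param a_f formative sensitivity, yr^-1 m^-2; > 0.
#' @param A,B,C,D decline-sensitivity coefficients; `D > 0`.
#' @param T_f formative-stage duration, years; > 0.
#' @param epsilon initial abundance in (0, 1).
#' @param n_e extinction threshold; 0 < `n_e` < `epsilon`.
#' @param t_ip inflection age, years, or `NULL`.
#' @param t_maxage maximum age, years.
#' @return An object of class `species_params`.
#' @examples
#' species_params()  # Table of calibrated white-birch defaults
#' @export
species_params <- function(lambda = 3.24, a_f = 0.49,
                           A = -0.024, B = 0.513, C = 7e-4, D = 0.04,
                           T_f = 1, epsilon = 0.05, n_e = 0.01,
                           t_ip = NULL, t_maxage = 60) {
  check_scalar(lambda, "lambda", positive = TRUE)
  check_scalar(a_f, "a_f", positive = TRUE)
  check_scalar(A, "A"); check_scalar(B, "B"); check_scalar(C, "C")
  check_scalar(D, "D", positive = TRUE)
  check_scalar(T_f, "T_f", positive = TRUE)
  check_scalar(epsilon, "epsilon", positive = TRUE)
  check_scalar(n_e, "n_e", positive = TRUE)
  check_scalar(t_maxage, "t_maxage", positive = TRUE)
  if (!(n_e < epsilon && epsilon < 1)) {
    stop("need 0 < n_e < epsilon < 1", call. = FALSE)
  }
  if (!is.null(t_ip)) {
    check_scalar(t_ip, "t_ip", positive = TRUE)
    if (!(T_f < t_ip && t_ip < t_maxage)) {
      stop("need T_f < t_ip < t_maxage", call. = FALSE)
    }
  }
  structure(list(lambda = lambda, a_f = a_f, A = A, B = B, C = C, D = D,
                 T_f = T_f, epsilon = epsilon, n_e = n_e,
                 t_ip = t_ip, t_maxage = t_maxage),
            class = "species_params")
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters:\n")
  cat("  lambda =", x$lambda, "yr^-1, a_f =", x$a_f, "yr^-1 m^-2, T_f =",
      x$T_f, "yr\n")
  cat("  a_d(t) = A + B/t + C*exp(D*t):  A =", x$A, " B =", x$B,
      " C =", x$C, " D =", x$D, "\n")
  cat("  epsilon =", x$epsilon, " n_e =", x$n_e, " t_maxage =", x$t_maxage, "yr\n")
  invisible(x)
}

#' Quadratic divergence of the water table from the favorable level
#'
#' The penalty for water-table departure from the plot's favorable level:
#' \eqn{D(h-\eta) = (h-\eta)^2} (m^2), the simplest concave-growth metric.
#'
#' @param h water level, metres (vectorized).
#' @param eta favorable level, metres.
#' @return Squared departure, m^2.
#' @export
divergence <- function(h, eta) (h - eta)^2

#' Stage-switched population growth rate
#'
#' \eqn{r(h,t) = \lambda - a_f D(h-\eta)} for \eqn{t \le T_f} (formative
#' stage, closed on the left at `T_f`), and \eqn{-a_d(t) D(h-\eta)} after
#' (decline stage).
#'
#' @param h water level, metres.
#' @param t age, years; must be > 0.
#' @param sp a [species_params()].
#' @param eta favorable level, metres.
#' @return Growth rate, yr^-1.
#' @export
growth_rate <- function(h, t, sp, eta) {
  stopifnot(inherits(sp, "species_params"))
  check_scalar(t, "t", positive = TRUE)
  d <- divergence(h, eta)
  if (t <= sp$T_f) sp$lambda - sp$a_f * d else -sensitivity(t, sp) * d
}

#' Time-varying decline-stage sensitivity
#'
#' \eqn{a_d(t) = A + B/t + C e^{Dt}}: the `B/t` term captures sensitivity
#' reduction as individuals grow, the `C e^{Dt}` term the sensitivity
#' increase with senescence, and `A` maintains continuity with the
#' formative stage. May be negative over an interval (the calibrated
#' white-birch coefficients give \eqn{a_d(t_{ip}) \approx -0.0086}), in
#' which window the decline-stage mean can locally rise.
#'
#' @param t age, years; must be > 0 (the `B/t` term is singular at 0).
#' @param sp a [species_params()].
#' @return Sensitivity, yr^-1 m^-2 (vectorized over `t`).
#' @export
sensitivity <- function(t, sp) {
  stopifnot(inherits(sp, "species_params"))
  if (any(t <= 0)) stop("`t` must be > 0", call. = FALSE)
  sp$A + sp$B / t + sp$C * exp(sp$D * t)
}

#' Integrals of the decline sensitivity
#'
#' `power = 1` uses the closed form
#' \eqn{A(t_1-t_0) + B\log(t_1/t_0) + (C/D)(e^{Dt_1}-e^{Dt_0})};
#' `power = 2` integrates \eqn{a_d(t)^2} by adaptive quadrature (absolute
#' tolerance 1e-10; the cross terms have no elementary antiderivative).
#'
#' @param t0,t1 integration limits, years; `0 < t0 <= t1`.
#' @param sp a [species_params()].
#' @param power 1 or 2.
#' @return The integral value.
#' @export
sensitivity_integral <- function(t0, t1, sp, power = 1) {
  stopifnot(inherits(sp, "species_params"))
  check_scalar(t0, "t0", positive = TRUE)
  check_scalar(t1, "t1")
  if (t1 < t0) stop("need t0 <= t1", call. = FALSE)
  if (t1 == t0) return(0)
  if (power == 1) {
    sp$A * (t1 - t0) + sp$B * log(t1 / t0) +
      (sp$C / sp$D) * (exp(sp$D * t1) - exp(sp$D * t0))
  } else if (power == 2) {
    stats::integrate(function(s) sensitivity(s, sp)^2, t0, t1,
                     abs.tol = 1e-10, rel.tol = 1e-10,
                     subdivisions = 1000L)$value
  } else {
    stop("`power` must be 1 or 2", call. = FALSE)
  }
}

#' Calibrate the decline-sensitivity coefficients from life-history traits
#'
#' Solves the four-constraint system
#' \eqn{a_d(T_f) = a_f} (continuity),
#' \eqn{a_d'(t_{ip}) = 0} (growth inflection),
#' \eqn{a_d(t_{ip}) = a_{d,min}} (minimum sensitivity of mature plants),
#' \eqn{a_d(t_{maxage}) = a_{d,max}} (sensitivity at maximum age)
#' for (A, B, C, D). For fixed `D` the value constraints are linear in
#' (A, B, C); the inflection residual is then a one-dimensional function of
#' `D`, bracketed on a log-spaced grid and solved by [stats::uniroot()].
#'
#' @param a_f formative sensitivity (continuity value at `T_f`).
#' @param T_f formative duration, years.
#' @param t_ip inflection age, years; `T_f < t_ip < t_maxage`.
#' @param ad_min sensitivity at the inflection age; must be < `min(a_f, ad_max)`.
#' @param t_maxage maximum age, years.
#' @param ad_max sensitivity at the maximum age.
#' @param D_range interval searched for `D` (yr^-1).
#' @return A list with `A`, `B`, `C`, `D` and the constraint `residual`
#'   (max absolute violation, < 1e-8 on success).
#' @export
calibrate_sensitivity <- function(a_f, T_f, t_ip, ad_min, t_maxage, ad_max,
                                  D_range = c(1e-4, 1)) {
  check_scalar(a_f, "a_f", positive = TRUE)
  check_scalar(T_f, "T_f", positive = TRUE)
  check_scalar(t_ip, "t_ip", positive = TRUE)
  check_scalar(t_maxage, "t_maxage", positive = TRUE)
  if (!(T_f < t_ip && t_ip < t_maxage)) stop("need T_f < t_ip < t_maxage", call. = FALSE)
  if (!(ad_min < min(a_f, ad_max))) {
    stop("infeasible constraints: need ad_min < min(a_f, ad_max)", call. = FALSE)
  }

  # Linear solve of the three value constraints for (A, B, C) at fixed D.
  abc_at <- function(D) {
    mat <- rbind(c(1, 1 / T_f, exp(D * T_f)),
                 c(1, 1 / t_ip, exp(D * t_ip)),
                 c(1, 1 / t_maxage, exp(D * t_maxage)))
    rhs <- c(a_f, ad_min, ad_max)
    tryCatch(solve(mat, rhs), error = function(e) rep(NA_real_, 3))
  }
  # Residual of a_d'(t_ip) = -B/t_ip^2 + C D exp(D t_ip) = 0.
  resid <- function(D) {
    abc <- abc_at(D)
    if (anyNA(abc)) return(NA_real_)
    -abc[2] / t_ip^2 + abc[3] * D * exp(D * t_ip)
  }

  Ds <- exp(seq(log(D_range[1]), log(D_range[2]), length.out = 200L))
  rs <- vapply(Ds, resid, numeric(1))
  ok <- which(is.finite(rs))
  flips <- ok[which(diff(sign(rs[ok])) != 0)]
  if (!length(flips)) {
    stop("calibrate_sensitivity: no sign change of the inflection residual ",
         "over D_range; constraint system infeasible", call. = FALSE)
  }
  i <- flips[1]
  root <- stats::uniroot(resid, lower = Ds[i], upper = Ds[i + 1L], tol = 1e-14)
  D <- root$root
  abc <- abc_at(D)
  ad <- function(t) abc[1] + abc[2] / t + abc[3] * exp(D * t)
  residual <- max(abs(c(ad(T_f) - a_f, ad(t_ip) - ad_min, ad(t_maxage) - ad_max,
                        -abc[2] / t_ip^2 + abc[3] * D * exp(D * t_ip))))
  if (!is.finite(residual) || residual > 1e-8) {
    stop("calibrate_sensitivity failed to meet the 1e-8 residual tolerance ",
         "(residual = ", signif(residual, 3), ")", call. = FALSE)
  }
  list(A = abc[1], B = abc[2], C = abc[3], D = D, residual = residual)
}
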