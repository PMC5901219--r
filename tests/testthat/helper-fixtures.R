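# Shared fixtures: the calibrated white-birch parameter set and its flow
# regime, used across modules.

birch <- species_params()                   # lambda 3.24, a_f 0.49, A..D
luan_regime <- flow_regime(mu = 82.8, sigma = 0.58, tau_h = 0)
birch_plots <- data.frame(plot_id = 1:3,
                          eta = c(83.03, 83.97, 84.67),
                          altitude = c(83.03, 83.97, 84.67),
                          distance = c(10, 40, 80))
eta_prime1 <- luan_regime$mu - birch_plots$eta[1]   # -0.23 m

# A species whose decline sensitivity stays strictly positive at all ages
# (the birch coefficients dip slightly negative near the inflection age),
# used for the lifespan-vs-divergence shape checks.
ad_pos_species <- species_params(A = 0.05, B = 0.45, C = 7e-4, D = 0.04)

# Closed-form deterministic logistic solution in the formative stage
# (noise off): independent oracle for the sigma -> 0 simulation limit.
logistic_solution <- function(t, lambda, a_f, eta_prime, epsilon) {
  r <- lambda - a_f * eta_prime^2
  1 / (1 + ((1 - epsilon) / epsilon) * exp(-r * t))
}
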