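# Example configuration: calibrated white-birch parameters on a
# stationary flow regime. Units: metres (levels), years (times).
flow:
  mu: 82.8        # mean flood water table, m
  sigma: 0.58     # sd of the water table, m
  tau_h: 0        # correlation time, yr (0 = white-noise limit)
species:
  lambda: 3.24    # max formative growth rate, 1/yr
  a_f: 0.49       # formative sensitivity, 1/(yr m^2)
  A: -0.024       # a_d(t) = A + B/t + C*exp(D*t)
  B: 0.513
  C: 7.0e-4
  D: 0.04
  T_f: 1          # formative-stage duration, yr
  epsilon: 0.05   # initial (germination) abundance
  n_e: 0.01       # extinction threshold
  t_maxage: 60
plots:
  - plot_id: 1
    eta: 83.03    # favorable water level, m
    altitude: 83.03
    distance: 10
  - plot_id: 2
    eta: 83.97
    altitude: 83.97
    distance: 40
  - plot_id: 3
    eta: 84.67
    altitude: 84.67
    distance: 80
simulation:
  dt: 0.01        # integration step, yr
  n_paths: 1000
  seed: 1
  t_end: 1
  years: 60
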