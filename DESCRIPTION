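Package: riparia
Title: Stochastic Cohort Dynamics of Riparian Vegetation Under River Flow
    Fluctuation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Temporally segmented stochastic modelling of same-aged
    (cohort) riparian plant populations driven by random flood water-table
    fluctuation. Provides white-Gaussian-noise and Ornstein-Uhlenbeck
    flow-regime machinery, closed-form logit-normal and log-normal
    abundance distributions with colored-noise variance corrections,
    Monte-Carlo cohort simulation, population lifespan via the
    mean-process stopping-time equation, spatial abundance and lifespan
    patterns along riparian transects, least-squares calibration of
    species parameters from plot samples, and multi-cohort age-structure
    simulation under piecewise-stationary (nonstationary) flow regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
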