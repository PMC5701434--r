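Package: latentexp
Title: Simulation of Total Symptom-Score Distributions from an Exponential Latent Trait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo and semi-analytic machinery for studying how the
    distribution of total scores on a binary symptom inventory (a CIS-R-like
    instrument with 14 items and 57 yes/no questions) inherits the shape of an
    exponentially distributed latent severity trait. Provides percentile-point
    calibration of per-question threshold means to symptom prevalence rates, a
    seeded simulator of the latent-versus-threshold comparison process, an
    exact Poisson-binomial mixture oracle for the total-score distribution,
    log-linear tail diagnostics (slope, R-squared, skewness), and a runner for
    the full condition grid over latent rates and threshold spreads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
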