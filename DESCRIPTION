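Package: cpsdyad
Title: Assessment of Dyadic Collaborative Problem Solving from Process
    Stream Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for scoring and modeling human-to-human collaborative
    problem solving (CPS) assessments from time-stamped event logs.
    Provides rule-based extraction of individual and group indicators
    from per-dyad process streams, discretization of frequency-based
    indicators by empirical cut-offs, and calibration of a within-item
    two-dimensional Rasch model (a multidimensional random coefficients
    multinomial logit model) in which the two dyad members are
    correlated latent dimensions. Includes marginal maximum likelihood
    estimation by EM with Gauss-Hermite quadrature, EAP ability
    estimation, infit mean-square item fit statistics with confidence
    intervals and standardized T values, separation and EAP
    reliabilities, a two-stage retention filter, Cohen's kappa
    validation of automatic scoring, Wright maps, and a seeded
    simulator that generates full synthetic event logs with planted
    indicator values for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
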