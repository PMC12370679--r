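Package: secbranch
Title: Secondary Branch Size Models for Planted Korean Pine Crowns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models of secondary (second-order) branch length and diameter
    within the crowns of planted Korean pine (Pinus koraiensis). Provides a
    hierarchical crown-data generator (trees, primary branches, secondary
    branch whorls), nine candidate growth functions with analytic gradients,
    nonlinear least-squares screening with covariate-expansion search, a
    two-level nonlinear mixed-effects estimator (Lindstrom-Bates alternating
    algorithm with a Laplace-approximate likelihood), log-log allometric
    scaling with percentile-bootstrap confidence intervals, and crown-profile
    summaries including the relative depth at which branch size peaks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    pracma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
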