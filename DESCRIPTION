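Package: spillpower
Title: Simulation-Based Power Analysis and Instrumental-Variable Decomposition of Behavioral Spillovers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing randomized experiments on
    behavioral spillovers between two sequential behaviors. Implements a
    latent-activation structural model of a targeted and a non-targeted
    behavior under randomized framing treatments and a choice-architecture
    nudge, Monte-Carlo calibration of the structural parameters to target
    Cohen's d effect sizes, simulation-based power analysis over sample-size
    grids, and the estimation pipeline that decomposes a treatment's total
    spillover effect into direct and indirect components via two-stage least
    squares with heteroskedasticity-robust inference and a studentized
    bootstrap confidence interval for the indirect effect. A synthetic
    respondent-table generator emulates the schema of the three-study
    experiment so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma,
    sandwich,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
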