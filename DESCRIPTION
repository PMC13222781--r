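Package: clpmscrutiny
Title: Scrutiny of Cross-Lagged Panel Associations via Difference-Score
    Multiverse Analysis and a Trait-State Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scrutinizing cross-lagged panel findings on two
    longitudinal constructs. Estimates three difference-score effect variants
    per exposure-outcome timeframe, both in closed form from correlations and
    by least-squares regression, pools them with a random-effects
    meta-analytic model, and fits the Model of Spurious Longitudinal
    Associations (MoSLA) -- a trait plus shared autocorrelated occasion-state
    structural equation model -- by full maximum likelihood with chi-square,
    CFI/TLI, RMSEA and its noncentral chi-square confidence interval.
    Includes simulators for panel data matching a target correlation matrix
    exactly, for the MoSLA generating process, and for a common-cause model
    with no direct cross-lagged path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
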