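Package: cuecurve
Title: Learning-Curve Analysis of Retro-Cue Change-Detection Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the retro-cue benefit in visual working
    memory change-detection tasks develops with practice. Provides an
    edge-shrinking moving average for binary trial outcomes, hierarchical
    Bayesian estimation of group accuracy per trial time, Cowan's k capacity
    transforms, competing growth-model fits (linear, exponential, logistic)
    compared by BIC with leave-one-observer-out robustness, plateau detection
    from the fitted derivative, per-trial-time effect sizes and directional
    default Bayes factors, and a synthetic-observer generator for parameter
    recovery and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
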