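Package: cocoflux
Title: Crossflow Microfiltration Modelling and Techno-Economics for Green
    Coconut Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for optimizing crossflow microfiltration of green coconut
    water and assessing the economics of a coconut biorefinery. Implements
    replicate-weighted quadratic response-surface fitting on a face-centered
    design with significance-based term pruning and ANOVA, a Levenberg-
    Marquardt trained 2-5-2 neural surrogate with L2 regularization, a bounded
    genetic algorithm for setpoint optimization, grouped leave-one-condition-
    out cross-validation with Q2 and RMSE_CV, resistance-in-series fouling
    partitioning, Hermia blocking-law analysis of flux decline, and a
    discounted-cash-flow techno-economic model with price sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
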