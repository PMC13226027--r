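Package: adsuppress
Title: Spatiotemporal Scaling and Network Analysis of Stimulation-Evoked
    After-Discharge Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline for multichannel after-discharge
    trial recordings: windowed detrended fluctuation analysis (DFA) and
    multifractal DFA scaling estimation, fractional-order dynamical network
    (FODN) identification with Grunwald-Letnikov derivatives and alternating
    ridge/LASSO fitting, dominant-eigenmode summarisation, phase-wise
    Kolmogorov-Smirnov distribution comparison, and leave-one-trial-out
    logistic-regression classification of suppression outcome. Includes a
    synthetic cohort generator (fractional Gaussian noise, ARFIMA,
    multiplicative cascades, planted coupling networks) that provides
    oracle inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
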