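Package: expotox
Title: Biological Indicators of Environmental Pollution Exposure from
    Sensor Panels and Health-Examination Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for linking smart-city environmental monitoring series
    (PM2.5, SO2, meteorology) to clinical indicator positivity in
    health-examination panels. Provides a synthetic panel generator with
    planted exposure-indicator correlations; min-max normalization,
    record cleaning, binary-relevance and label-powerset multi-label
    transforms, and a Pearson-weighted association loss; classical
    seasonal decomposition and dynamic factor analysis of pollutant
    series with Nash-Sutcliffe and AIC model selection; a
    group-convolution neural classifier for exam-feature vectors; a
    gated recurrent unit forecaster whose input features and
    hyperparameters are tuned by a real-coded genetic algorithm; and
    quarterly exposure-association tables with correlation-based
    indicator identification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
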