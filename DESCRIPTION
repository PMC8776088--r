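Package: wxmort
Title: Data-Enhancement Strategies for Weather-Related Health Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to enhance daily health-count and temperature time series
    before epidemiological regression. Implements four strategies: causal
    Epanechnikov aggregation of the health response combined with a
    distributed lag non-linear model (DLNM) and an AIC-selected autoregressive
    residual model; noise-assisted multivariate empirical mode decomposition
    of the exposure followed by a Poisson Lasso over the intrinsic mode
    functions; a functional historical linear model on annual curves fitted by
    component-wise gradient boosting; and a scalar-on-function model linking
    daily mortality to the previous day's hourly temperature curve. Includes a
    benchmark DLNM, a seeded synthetic weather-mortality generator with known
    ground truth, and an hv-block (leave-one-year-out) cross-validation
    harness producing day-of-year relative RMSE curves with circular LOESS
    smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    splines,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
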