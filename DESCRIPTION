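Package: nichedyn
Title: Temporal Dynamics of Estimated Environmental Niche Hypervolumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how estimated environmental niches of species change
    over time. Fits annual and pooled presence-absence ecological niche
    models (quadratic logistic regression, penalized additive models, random
    forests, and boosted regression trees), converts each fitted model into a
    three-dimensional niche hypervolume by rejection sampling and
    kernel-density boundary estimation, compares annual to pooled
    hypervolumes with six distance, volume, and dissimilarity metrics, and
    relates annual metric values to candidate drivers (abundance, occurrence,
    sampling effort, temperature, salinity, red-tide severity, and modelling
    algorithm) with linear mixed-effects models that include a species random
    intercept and temporal autocorrelation. A synthetic-data module emulates
    a multi-year bottom-trawl survey with virtual species whose occupancy
    follows known Gaussian niche response surfaces, so the whole pipeline is
    testable against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    nlme,
    randomForest,
    xgboost,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
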