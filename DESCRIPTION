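Package: fvsdecode
Title: Automated Model Ranking and Greedy Forward Variable Selection for
    Tabular Decoding
Version: 0.1.0
Authors@R:
    person("fvsdecode", "maintainers", email = "fvsdecode@example.org",
           role = c("aut", "cre"))
Description: Two-stage decoding pipeline for high-dimensional tabular data
    such as region-of-interest gray-matter volume tables. Stage one ranks a
    fixed zoo of regression and classification models (penalized linear
    models, kernel methods, Gaussian processes, and tree ensembles built on
    an internal CART engine) after nested hyperparameter tuning by grid or
    random search with k-fold cross-validation. Stage two runs greedy
    forward variable selection with per-iteration train/test resplitting to
    find a minimal feature subset maximizing held-out performance, with a
    Boruta shadow-feature selector as an all-relevant counterpart.
    Covariates of no interest (for example total intracranial volume) are
    removed by leakage-safe residualization. Includes a synthetic-data
    generator emulating correlated ROI tables with planted signal, full
    regression and classification metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    glmnet,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
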