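Package: pcmdif
Title: Partial Credit Model Calibration, Category Diagnostics, and
    Lasso-Penalized Differential Item Functioning for Ordinal Rating Scales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for item-level psychometric analysis of polytomous
    rating scales such as the 15-item Childhood Autism Rating Scale
    (first edition). Implements joint maximum likelihood calibration of
    the Partial Credit Model, Andrich-threshold category diagnostics with
    rescoring by category collapsing, infit/outfit mean-square and
    standardized fit statistics, separation and reliability indices, a
    text Wright map, principal component analysis of standardized
    residuals for unidimensionality assessment, uniform differential item
    functioning detection via a lasso-penalized Generalized Partial
    Credit Model with BIC selection along the penalty path, and
    scale-level group comparisons. Includes a synthetic-data generator
    that emulates a large clinical referral sample with known person and
    item parameters and optional planted DIF.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
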