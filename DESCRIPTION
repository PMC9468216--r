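Package: mmdbn
Title: Bayesian-Network Analysis of Multimorbidity Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multimorbidity (the co-occurrence of two or
    more chronic conditions) in categorical survey cohorts. The package codes
    raw survey fields into integer-scored study variables (including IPAQ
    MET-minute physical-activity bands and the two-or-more-conditions
    multimorbidity flag), imputes missing categorical values with an
    iterative random-forest scheme, fits a multivariable logistic baseline by
    iteratively reweighted least squares, learns a discrete Bayesian-network
    structure with the Max-Min Hill-Climbing hybrid algorithm (G-squared
    conditional-independence tests plus BIC-scored hill climbing), estimates
    conditional probability tables by maximum likelihood, and answers
    sequential risk queries by exact variable-elimination inference. A
    synthetic-cohort generator samples survey-like data from a configurable
    ground-truth network so that every stage of the pipeline can be exercised
    and tested without access to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
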