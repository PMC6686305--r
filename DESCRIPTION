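Package: temponull
Title: Temporal Species Co-Occurrence Null Models for Community Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Null-model analysis of temporal species associations in
    species-by-year community matrices. Implements the binary co-occurrence
    indices (number of checkerboard species pairs, checkerboard score,
    variance ratio) with fixed-equiprobable (SIM2) and fixed-fixed sequential
    swap (SIM9) randomizations, and the quantitative indices (standardized
    abundance checkerboards and aggregations, multi-community Morisita-Horn
    similarity) with individual-based IT and IA randomizations, together with
    empirical tail tests and a three-way outcome classification
    (aggregation / segregation / random). Outcomes across data sets and
    foraging guilds feed Bayesian binomial and multinomial (mixed) logistic
    meta-analyses with Cauchy priors, fitted by an adaptive random-walk
    Metropolis sampler, compared by DIC. A synthetic community generator
    produces matrices with compensatory, correlated, or random dynamics so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
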