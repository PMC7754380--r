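Package: misnma
Title: Bayesian Network Meta-Analysis with Informative Missing Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Random-effects network meta-analysis for binary outcomes that
    models missing outcome data through the informative missingness odds
    ratio (IMOR), under both pattern-mixture and selection factorizations of
    the joint outcome/missingness distribution. Six prior structures for the
    log IMOR (identical or hierarchical, crossed with intervention-specific,
    trial-specific and common-within-network scope) are supported, together
    with node-splitting for local inconsistency, treatment-ranking
    probabilities, an adaptive Metropolis-within-Gibbs sampler with
    Gelman-Rubin diagnostics, and a simulator for triangle networks of
    two-arm trials with informative or missing-at-random dropout.
License: MIT
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
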