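Package: rxnbo
Title: Closed-Loop Bayesian Optimization of Reaction Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop Bayesian optimization of chemical reaction
    conditions over mixed continuous/ordinal/categorical design spaces, built
    around a Gaussian-process surrogate and an expected-improvement acquisition
    with a dual exploration (xi) schedule.  Includes Latin-hypercube initial
    designs, PCA-based ordinal encoding of reagents from physicochemical
    descriptor tables, transfer learning across substrates via a task
    categorical variable, and a synthetic consecutive-acylation yield
    simulator so full optimization campaigns can be run and benchmarked
    without laboratory hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
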