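Package: herdmaps
Title: Bayesian Mapping of Livestock-to-Human Density from Household Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based geostatistics for livestock density defined as the
    ratio of animals to humans. Fits zero-inflated Poisson Bayesian
    hierarchical models to cluster-level household-survey counts with a
    Matern (nu = 1) spatial field approximated by the SPDE finite-element
    method, structured temporal (random walk) and separable space-time
    effects, and penalized-complexity priors; predicts posterior median and
    credible-interval-width density surfaces on a regular grid; performs
    survey-stratified cross-validation for model selection; and provides a
    design-based small-area-estimation stage (Horvitz-Thompson ratio
    estimates, delta-method log transform, ICAR spatial smoothing) for
    census data geolocated only to administrative areas. A synthetic-data
    generator draws surveys and weighted censuses from the same generative
    model so that every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
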