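Package: dispersim
Title: Models of Human Dispersion Estimation from Small Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A complete pipeline for studying how observers estimate the
    dispersion of future events from four observations: renormalized stimulus
    generation, a Bayesian ideal-observer benchmark with capture-probability
    feedback, a zoo of inference and heuristic response models (maximum, range,
    weighting, normal, generalized normal, Gaussian kernel density estimation
    and its delta limit, tiling, history and baseline regressors), a Gaussian
    process regression predictability ceiling, a heteroscedastic lapse-mixture
    response likelihood, stratified repeated cross-validated model evidence in
    decibans, and hierarchical Bayesian group-level model selection with
    exceedance probabilities. Includes a synthetic-cohort generator so the full
    pipeline can be exercised and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
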