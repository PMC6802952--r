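Package: scenersa
Title: Spatiotemporally Resolved Representational Similarity Analysis of
    Fragmented Scene Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) of
    multivariate neural responses to scene fragments, resolved across
    cortical regions (fMRI) and time (EEG). Builds neural
    representational dissimilarity matrices (RDMs) via split-half
    cross-validated correlation differences (fMRI) and pairwise linear
    discriminant decoding with leave-one-trial-out cross-validation
    (EEG); models them with binary location and scene-category
    predictor RDMs in per-subject general linear models, optionally
    after residualizing against a bank of feature-model RDMs or
    restricting to cross-scene-type condition pairs; and performs
    group-level inference with one-tailed t-tests, Bonferroni
    correction, threshold-free cluster enhancement (TFCE) and
    max-statistic sign-permutation testing, including bootstrap onset
    and peak latencies. A synthetic-data generator with planted
    representational structure makes the full pipeline testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
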