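Package: gaitswarm
Title: Gait Recognition with Swarm-Tuned Weighted Regularized
    Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Hybrid gait-recognition pipeline for model-based gait
    biometrics: a weighted regularized discriminant analysis (RDA)
    classifier whose per-observation weights and hyperparameters (the
    coefficient threshold delta and covariance regularization gamma) are
    tuned by particle swarm optimization, grey wolf optimization, or the
    whale optimization algorithm against a validation confusion
    objective.  Includes multilinear principal component analysis (MPCA)
    for reducing 32 x 11 x 3 gait-signature tensors, a synthetic
    generator emulating the structure of marker-less motion-capture gait
    datasets (classes, covariate shifts such as clothing change and
    backpack, smoothed sensor noise), hold-out and 10-fold
    cross-validation experiment protocols, and broom-style tidiers plus
    ggplot2 autoplot methods for every result type.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
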