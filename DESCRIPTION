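Package: sleepscope
Title: Sleep Substate Classification and Neural Dynamics in Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for partitioning larval-fish locomotor quiescence into sleep
    substates from eye-movement kinematics, and for characterizing the neural
    dynamics of eye-movement sleep. Includes conjugate-saccade detection with
    fused-lasso (total-variation) denoising, Gaussian-mixture substate
    classification with sample-size-adjusted BIC model selection, a
    latent-variable neural-network model of circadian and luminosity gating
    with input-ablation analysis, calcium-trace post-processing (duplicate
    merging, bleach correction, transient-event detection), per-neuron
    encoding regression, exponential ramp classification, anatomical
    enrichment, state-restricted PCA with a trajectory-entanglement statistic,
    elastic-net relative-time decoding, and a synthetic-data generator that
    emulates the statistical structure of the behavioral and neural
    recordings so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    EBImage,
    jsonlite,
    glmnet,
    tiff,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
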