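Package: eluent
Title: Prediction of Normal-Phase Chromatography Solvent Systems from Reaction SMILES
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds and evaluates a two-stage machine-learning pipeline that
    proposes normal-phase column chromatography purification conditions for
    organic reactions. A multilabel classifier predicts the one- or two-solvent
    eluent system from the reaction SMILES, and, for two-solvent systems, a
    regressor predicts the normalized mixing ratio. Includes mining of solvent
    labels and ratios from raw purification text, dataset assembly with
    stratified splitting and molecule-permutation augmentation, three reaction
    vectorizations (learned character embeddings, multi-molecule
    extended-connectivity fingerprint matrices, and fingerprint auto-encoder
    latents), a small neural-network engine (dense, 1D-convolutional and LSTM
    layers trained with Adam), classification and regression baselines and
    metrics, and a synthetic reaction generator with planted functional-group
    rules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
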