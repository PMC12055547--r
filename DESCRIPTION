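Package: cardiofed
Title: Federated Privacy-Preserving Multimodal Cardiac Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and training framework for privacy-preserving, federated
    classification of cardiac disease from multimodal data (ECG traces, cardiac
    image grids, patient records and nutrition logs). Provides a synthetic cohort
    generator with controllable class separation, signal/image/record preprocessing
    (median filtering, brick-wall band-pass, FastICA source separation, min-max
    scaling, k-means diet clustering), per-modality feature extraction, trainable
    softmax attention fusion, a from-scratch feed-forward network trained with
    SGD-with-momentum, federated averaging with Gaussian-mechanism differential
    privacy, a confusion-matrix metric suite with paired significance tests, and a
    deep Q-network diet recommender validated against exact value iteration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
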