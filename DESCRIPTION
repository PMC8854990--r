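Package: idgcn
Title: Invertible Dynamic Graph Convolutional Networks for Brain
    Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies subjects from functional brain-connectivity
    features with an invertible dynamic graph convolutional network:
    Chebyshev spectral graph convolutions on k-nearest functional and
    spatial graphs are composed inside additive invertible blocks, so the
    input connectivity features can be reconstructed exactly from the
    network output for biomarker interpretation. Includes sliding-window
    dynamic connectivity features, per-region random-forest feature
    pre-screening, stratified cross-validated training and evaluation,
    reconstruction-based edge importance and node-lesion importance, a
    synthetic-cohort generator with planted effects for validation, and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ranger,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
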