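Package: cellmiml
Title: Multimodal Image-Mechanics Learning for Label-Free Cell Classification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Label-free classification of cells transiting a microfluidic
    constriction, fusing convolutional image embeddings with biomechanical
    features (deformation index, transition time, peak velocity, deformation
    rate). Includes a stiffness-parameterised phenomenological transit
    simulator and synthetic frame renderer, image-based feature extraction,
    a classical tabular-classifier comparison, a residual convolutional
    encoder and multimodal fusion network trained with an in-package
    backpropagation engine, grouped stratified cross-validation, transfer
    learning, Grad-CAM and latent-space diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    png,
    Rtsne,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
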