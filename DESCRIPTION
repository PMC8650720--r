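Package: nigrastab
Title: Label-Stability Analysis for Substantia Nigra Conditioned QSM Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and improve the stability of Parkinson's disease
    classifiers that condition on substantia nigra (SN) labels in quantitative
    susceptibility mapping (QSM) images. Provides a synthetic phantom cohort
    generator, Dice-controlled label perturbation through smooth random
    deformation fields, a radiomics plus logistic-regression baseline with an
    ICC(2,1) robustness screen and recursive feature elimination, compact 3D
    convolutional classifiers with masked-input and gated-pooling conditioning,
    a pooling-free coarse-to-fine segmentation network with a signed-distance
    head, a jointly trained end-to-end diagnosis model using a piecewise-linear
    probability gate, and an experiment harness computing classification
    stability tables and the classification consistency index (CCI) under
    nested cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    glmnet,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
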