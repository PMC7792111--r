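Package: uapkit
Title: Universal Adversarial Perturbation Analysis for Image Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the vulnerability of image-classification
    networks to universal adversarial perturbations (UAPs). Implements
    nontargeted and targeted UAP generation by iterative fast-gradient-sign
    updates under an L2 or L-infinity norm budget, random-perturbation
    controls sampled from the norm sphere, fooling-rate and targeted
    success-rate evaluation with row-normalized confusion matrices and
    cross-model transferability tables, and an adversarial-retraining
    defense loop. Ships a seeded synthetic image-task generator (blob,
    stripe and texture families, balanced or imbalanced, grayscale or RGB)
    and a small trainable convolutional network with exact input-pixel
    gradients, so the whole attack/defense pipeline runs end-to-end on a
    single CPU without external datasets or pretrained weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'constructors.R'
    'utils.R'
    'classifier.R'
    'attack.R'
    'evaluation.R'
    'defense.R'
    'synthetic-data.R'
    'orchestration.R'
    'uapkit-package.R'
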