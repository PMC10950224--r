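Package: murmil
Title: Multiple-Instance Learning and Explainable Features for Heart
    Murmur Detection in Phonocardiograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage, explainability-oriented detection of heart murmurs
    in phonocardiogram (PCG) recordings. Stage one localizes murmurs from
    weak recording-level labels with a multiple-instance-learning 1D U-Net
    (softmax pooling of per-sample "murmurness"), and a pooling-based
    convolutional network (PANN) turns single recordings into compact
    feature vectors. Stage two fuses PANN features, a 622-dimensional
    handcrafted feature set reduced to 22 by gradient-boosted importance,
    and demographics into a patient-level multitask classifier for murmur
    presence and clinical outcome. Includes a synthetic PCG generator with
    exact phase and murmur ground truth, the full preprocessing and
    augmentation chains, heart-phase segmentation utilities, quantitative
    explainability evaluation, and cost-weighted clinical metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    xgboost,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
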