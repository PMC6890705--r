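Package: myxoclass
Title: Automated Identification of Myxobacterial Genera from Fruiting-Body
    Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classification of myxobacterial genera and suborders from
    stereomicroscope images of fruiting bodies.  Implements a small
    convolutional neural network feature extractor whose fully-connected
    softmax head can be swapped for alternative classifier heads (the
    hybrid "E-CNN" design), including a bespoke extreme-learning-machine
    family (ELM, kernel ELM, constrained ELM, and online-sequential ELM)
    alongside adapters for SVM, multilayer-perceptron, RBF-network and
    gradient-boosted-tree heads.  Ships the 30-genus taxonomy registry,
    image preprocessing (grayscale conversion, size normalisation, crop
    augmentation), stratified k-fold cross-validation with confusion-matrix
    metrics, and a morphotype-driven synthetic fruiting-body image
    generator for end-to-end testing when real image collections are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    nnet,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
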