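Package: wellfate
Title: Label-Free Cell Fate Calling in Brightfield Microwell Time-Lapses
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pipeline for label-free monitoring of the earliest steps of the
    tumorsphere assay: single cancer stem-like cells isolated in ~200 um
    agarose microwells are imaged in brightfield over 96 h, each frame is
    classified as Single, Multiple, Death or Empty by either a small
    convolutional neural network (implemented from scratch on BLAS-backed
    C++ primitives) or a classical computer-vision baseline (Otsu
    thresholding, size and border filtering, ellipse fitting, rule-based
    decision), and a temporal decision tree turns the per-frame class
    probability series of each well into a fate call (division, death or
    quiescence) with an event time. Population dynamics (cumulative event
    percentages and sliding-window event rates), evaluation metrics
    (confusion matrix, accuracy, per-class recall and precision), a fully
    annotated synthetic microwell image generator, minimal grayscale TIFF
    stack input/output and a command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
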