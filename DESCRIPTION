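Package: woundseg
Title: Certainty-Weighted Semantic Segmentation of Forensic Skin Wounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for semantic segmentation and
    classification of skin wounds on forensic photographs. Implements a
    class-frequency- and annotation-certainty-weighted binary cross-entropy
    loss, the focal Tversky loss and their combinations; parsing and
    rasterization of VGG Image Annotator (VIA) polygon annotations with
    wound-class and certainty attributes; confusion-matrix based mean pixel
    accuracy and mean intersection-over-union evaluation; sevenfold
    cross-validation training of compact U-Net- and FPN-style
    encoder-decoder networks with dual checkpointing; and a seeded
    synthetic wound-photograph generator that emulates the statistical
    structure of forensic wound datasets (extreme class imbalance, fuzzy
    boundaries, distractors, per-region certainty labels) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nnet,
    optparse
Config/testthat/edition: 3
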