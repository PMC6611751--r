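Package: gleasonpatch
Title: Patch-Based Gleason Pattern Classification and Grade Group Determination for Prostate Biopsy Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for whole-slide Gleason grading of prostate
    needle biopsies: polygon-annotation-driven extraction of 299x299 pixel
    patches labeled by their central pixel, dihedral data augmentation,
    balanced biopsy-exclusive four-fold partitioning, a pluggable four-class
    patch classifier with desk-scale reference backends, support-vector-machine
    fusion of the four class probabilities into three decision classes,
    per-class probability maps, and rule-based adjusted grade-group
    determination from Gleason-pattern patch fractions with a 4.5% presence
    threshold. Includes evaluation statistics (confusion matrices, dichotomized
    sensitivity/specificity/F-measure, concordance, quadratic weighted kappa)
    and a procedural generator of annotated pseudo-histology slides for fully
    self-contained end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
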