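Package: fundusSA
Title: Scale-Adaptive Auto-Encoder Resizing and Grading of Retinal Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading age-related macular degeneration (AMD) from
    color retinal fundus photographs of heterogeneous sizes. Implements a
    scale-adaptive auto-encoder that maps an arbitrarily sized fundus image to
    a fixed 224x224x3 representation while jointly reconstructing a
    high-resolution image under a weighted dual loss (Pseudo-Huber, log-cosh,
    MSE or MSLE on each branch), a four-grade classification network (a
    pluggable convolutional backbone with a dense batch-normalized head), a
    synthetic fundus image generator with grade-conditional lesions, and an
    evaluation harness with micro-averaged confusion metrics, ROC/AUC and
    stratified k-fold cross-validation. All networks are trained with a
    self-contained CPU implementation; no external deep-learning runtime is
    required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
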