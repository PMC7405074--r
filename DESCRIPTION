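Package: ethomotif
Title: Bout Segmentation, Behavioral Module Clustering, and Motif
    Discovery for Animal Activity Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyzes one-dimensional animal-activity recordings (per-frame
    delta-pixel counts, e.g. from larval zebrafish in multi-well plates) in
    three stages: segmentation of each trace into alternating active and
    inactive bouts with a six-feature description of every active bout;
    unsupervised grouping of bouts into behavioral modules by evidence
    accumulation over an ensemble of Gaussian mixture models; and discovery
    of recurrent module motifs by hierarchical compression, with
    shuffle-normalized enrichment scores and supervised motif selection
    (mRMR ranking plus cross-validated linear discriminant classifiers).
    Includes a seeded synthetic-data generator with planted modules and
    motifs for end-to-end validation, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    MASS,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
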