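Package: mixcc
Title: Mixup-Based Sibling Contrastive Clustering of Short Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised clustering of short documents by jointly optimizing a
    sibling-instance contrastive objective and a Student-t anchor clustering
    head over augmented text views. Each mini-batch is augmented twice (word
    deletion, character noise, or a pluggable mask-and-fill predictor), a third
    virtual view is built by representation-level mixup of the anchor and the
    two views, and an InfoNCE-style loss with sibling-anchored negatives is
    combined with a Kullback-Leibler sharpening loss against learnable
    centroids initialized by k-means. Includes a deterministic synthetic
    topic-corpus generator, Hungarian-matched clustering accuracy and
    normalized mutual information, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
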