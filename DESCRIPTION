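Package: trackCBC
Title: Classifier-Based Clustering of Tracking Output for Animal
    Re-Identification in Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-identifies individual animals in a video by post-clustering
    the tracks produced by a multiple-object tracker. Tracks are merged down
    to a desired number of identities with a classifier-based clustering
    procedure driven by a masked, row-scaled resubstitution confusion matrix,
    under cannot-link constraints between tracks that co-occur in a frame.
    Includes a 54-dimensional RGB grid appearance descriptor, an IoU-gated
    Hungarian track builder, external clustering metrics (adjusted Rand
    index, normalised mutual information, counting and Hungarian accuracy)
    with a label sanity battery, comparator clustering baselines, an
    incremental Friedman ranking procedure, and a synthetic multi-animal
    scene simulator for end-to-end testing without video data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    clue,
    mclust,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
biocViews: Clustering, Classification, CellTracking
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
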