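Package: loopshift
Title: Stage-Resolved CTCF Loop Dynamics from Contact Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for chromatin-loop dynamics across an ordered
    differentiation time course. Reads binned sparse contact matrices, loop
    lists (BEDPE), peak sets (BED) and signal tracks (bedGraph); performs
    library-size subsampling, Knight-Ruiz and vanilla-coverage-sqrt matrix
    balancing, distance (observed/expected) normalization and A/B compartment
    eigenvector analysis; scores loops by aggregate peak analysis (APA) and
    meta scores; calls differential and stage-specific loops with an exact
    negative-binomial test; classifies anchor changes, annotates anchor
    chromatin occupancy with a permutation overlap test; partitions ATAC
    fragments by size, classifies enhancers and scores 25-kb H3K9me3 bins.
    Ships a synthetic multi-stage data generator with planted ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
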