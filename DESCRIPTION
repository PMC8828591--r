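Package: darktaxa
Title: Retrospective Audit of Kingdom-Level Taxonomic Annotations in
    Barcode Sequence Corpora
Version: 1.0.0
Authors@R:
    person("Kai", "Sandvik", email = "kai.sandvik@example.org",
           role = c("aut", "cre"))
Description: Tools to audit the annotation gap in DNA barcode corpora such
    as fungal ITS collections. Given sequences with release dates and
    seven-rank taxonomic lineages, the package clusters them into 80
    percent identity compound clusters sub-partitioned into single-linkage
    species hypotheses, assigns conflict-aware consensus taxonomies, and
    replays deposition history to decide, for every sequence annotated
    only at the kingdom level, whether a more resolved name was already
    available at deposition time (classifying it as a true positive or a
    close/reasonable-match false negative). A synthetic corpus generator
    with planted ground truth, metadata analyses (mycologist scoring,
    country comparison, yearly trends) and a command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
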