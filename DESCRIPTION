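Package: ordermem
Title: Sequence-Memory Scoring and Temporal-Contiguity Analysis for Free Recall
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for free-recall experiments in which recall is
    followed by an explicit ordering task. Classifies recalled word pairs by
    their contiguity at encoding and at retrieval (cont-enc-ret, cont-ret,
    cont-enc, first-three), selects an item-disjoint and category-balanced set
    of pairs by exact combinatorial search, scores explicit sequence memory
    (relative order, normalized absolute placement, inter-item distance),
    indexes reliance on internally-driven temporal context with the temporal
    clustering score, and runs the group-level repeated-measures contrasts,
    splits and (partial) correlations over subject summaries. Includes a
    generative simulator of participants with known contiguity, binding and
    placement-noise parameters for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
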