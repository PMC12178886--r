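Package: boxconcord
Title: Multi-Annotator Concordance Analysis for Bounding-Box Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating agreement between an object-detection model
    and groups of human annotators who draw bounding boxes on survey imagery.
    Annotations from all raters are clustered into unique physical objects by
    greedy mean-IoU agglomeration, a consensus "truth" label is adjudicated per
    object under two deterministic vote-counting rule sets, and the full
    evaluation surface is computed: per-object confidence scores, confusion
    tables against consensus truth (including a "not observed" class),
    accuracy/precision/recall/F1, single-operating-point ROC/AUC, intraclass
    correlation of per-image counts between and within rater groups, and
    rank-based group comparisons, all optionally stratified by an image
    quality score. A synthetic multi-annotator data generator with a known
    ground-truth ledger makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
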