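Package: devrecap
Title: Recapitulation of Embryonic Expression Programs in Insect Metamorphosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether the pupal transcriptome of a
    holometabolous insect reverts toward the embryonic expression state.
    Reads gene-by-sample FPKM matrices and sample metadata, applies the
    stage-coverage quality filters used in developmental time courses
    (female exclusion, duplicate-sample removal), and computes Spearman
    stage-similarity matrices, embryo-similarity profiles, stage-transition
    log fold changes and their cross-transition recapitulation correlation,
    gene-subset resampling nulls with empirical p-values, classification of
    four-stage trajectories against the 27 up/same/down step templates with
    zigzag-gene extraction, hierarchical profile clustering for dense time
    courses, and Fisher GO over-representation with Benjamini-Hochberg
    adjustment over an ontology parsed from OBO. A synthetic
    developmental-transcriptome generator with planted gene classes and
    ground truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
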