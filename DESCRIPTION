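Package: scAgeStates
Title: Chronological Aging States and Senescence Trajectory Analysis for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for chronological single-cell aging-clock
    analysis of a stem-cell-enriched epithelial population. Provides
    UMI-count quality control with spike-in, mitochondrial and stromal
    contaminant filters; log-normalization with covariate regression;
    one-dimensional pseudotime inference with segmentation of cells into
    four states (active young, quiescent young, early senescence, late
    senescence) from intersecting cluster-average expression curves;
    gene-set module scoring (SASP, pathways, pluripotency) with
    expression-matched controls; cell-cycle phase calling including a G0
    rule; six-pattern pathway-dynamics classification; consensus
    hypergeometric transcription-factor regulon enrichment and directional
    regulon activity scores; single-cell signaling entropy on a gene
    co-expression network; and single-hit limiting-dilution frequency
    estimation with confidence intervals and group comparison. A
    negative-binomial synthetic-data generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    splines,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
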