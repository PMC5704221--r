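Package: grnrewire
Title: Gene Regulatory Network Construction and Rewiring Analysis from
    Chromatin Accessibility Peaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds transcription-factor-to-gene regulatory networks from
    chromatin accessibility peaks (ATAC-seq or DNase-seq) by assigning peaks
    to genes within a fixed window of the transcription start site, scanning
    peak sequences with position weight matrices under an exact
    dynamic-programming null model for motif p-values, and joining binding
    evidence into a directed network. Provides hub-regulator ranking by
    out-degree and by PageRank on the reversed network, multi-network set
    intersections, receptor regulatory subnetworks, differential (rewired)
    networks between two cell conditions, local hypergeometric
    over-representation analysis, and a differential-expression screen for
    modulated genes. Includes a fully self-contained synthetic-data generator
    with planted binding sites and known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
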