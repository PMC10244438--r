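Package: seconsensus
Title: Super-Enhancer Identification, Differential Dynamics and Consensus
    Target Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies super-enhancers (SEs) from enhancer peak calls and
    genome-wide coverage using the ROSE-style procedure: peaks are stitched
    within a fixed genomic distance, stitched regions are ranked by
    integrated signal, and the SE/TE partition is set by the slope-1 tangent
    point of the scaled rank-signal ("hockey-stick") curve. Classifies SEs
    as condition-gain, condition-lost or shared by presence/absence overlap,
    intersects gain sets across multiple datasets into a consensus, annotates
    regions to nearest transcription start sites, and intersects SE target
    genes with upregulated and disease differential-expression gene sets to
    nominate candidate regulators. Includes RPKM coverage normalization,
    computeMatrix-style profile matrices, a synthetic multi-dataset study
    generator with planted ground truth, and a config-driven end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    rtracklayer,
    optparse
Config/testthat/edition: 3
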