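Package: ednanet
Title: Co-Occurrence Network Analysis of Multilocus eDNA Metabarcoding Time
    Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for environmental DNA (eDNA) metabarcoding
    time series: site-occupancy filtering of OTUs from PCR replicate detection
    histories, proportional decontamination against negative controls with
    Bray-Curtis replicate quality control, a per-locus eDNA abundance index
    combined across loci into an ensemble index, pairwise Kendall tau-b
    correlation calibrated against a dataset-permutation null with
    Benjamini-Hochberg control, weighted co-occurrence network construction
    (soft-threshold adjacency, topological overlap, dendrogram branch cutting
    into subnetworks), and association of subnetworks and taxa with
    environmental covariates. Includes a synthetic multi-locus community
    generator with planted subnetworks, amplification bias, contamination and
    linked environmental variables for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr
Config/testthat/edition: 3
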