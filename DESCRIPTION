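Package: pkstrack
Title: Strain Tracking and Pathway Presence/Absence Pattern Analysis for
    Longitudinal Metagenomes
Version: 0.1.0
Authors@R:
    person("PKS", "Maintainers", email = "maintainers@pkstrack.org",
           role = c("aut", "cre"))
Description: Tools to follow a dominant microbial strain through a series of
    metagenomic samples from one individual and to detect early signs of
    strain-community dysbiosis.  Strain identity between two samples is
    scored by window-based single-nucleotide-variant similarity (WSS)
    against a species reference, with per-species cutoff calibration.
    Metabolic capacity of the tracked strain is summarized as the pattern of
    presence/absence of KEGG pathways (PKS), inferred parsimoniously from
    EC-number gene annotations by minimum pathway set cover.  Longitudinal
    PKS vectors are compared by Hamming distance and scanned for clusters of
    identical patterns, extinction/reappearance events, and resolution to a
    unique pattern.  Includes seeded FASTQ quality filtering and
    subsampling, rarefaction-depth selection, synthetic data generators with
    planted ground truth, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    S4Vectors,
    VariantAnnotation,
    jsonlite,
    methods,
    rtracklayer,
    SummarizedExperiment,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
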