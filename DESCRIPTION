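Package: cistromics
Title: Cistrome-Transcriptome Integration for Transcription-Factor
    Co-Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating ChIP-seq cistromes with expression
    data: peak-set partitioning into common and factor-specific sites,
    treatment dynamics (lost/shared/gained peaks), TSS-window occupancy
    classification of genes, resampling-based enrichment odds ratios,
    distance-decayed regulatory-potential scoring with binding-association
    curves, super-enhancer stitching and hockey-stick ranking, binned
    signal pileups around peak centers, and per-sample gene-signature
    z-scores. Includes a fully seeded synthetic-data generator with
    planted ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
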