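Package: methylsensor
Title: Methylome Classification and Heterochromatin-Sensor Intron Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome bisulfite sequencing call
    tables: binomial methylation calling against a control-derived
    non-conversion rate, gene-body methylation (gbM) classification with
    per-context background models, detection of mCHG-enriched introns
    acting as heterochromatin sensors, population-scale ectopic non-CG
    gene scanning across accession panels, CWG strand-symmetry analysis,
    weighted-methylation metaplots, region-stratified population-genetic
    statistics (SNP density, Tajima's D), and short/long isoform-ratio
    analysis for genes with long methylated introns. Ships a synthetic
    methylome generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
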