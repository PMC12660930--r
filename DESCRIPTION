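Package: snmctkit
Title: Single-Nucleus Joint Methylome and Transcriptome Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for joint single-nucleus methylome and
    transcriptome (snmCT-seq style) experiments in pollen: nucleus-level
    quality control (RNA depth, genome bin coverage, organelle read
    fraction), coverage-based doublet censoring exploiting haploidy,
    chloroplast-based bisulfite conversion QC, marker-score cluster
    assignment with mature-VN/SN doublet reassignment, per-nucleus and
    pseudobulk region methylation statistics, metaplot profiles, mC density
    bins, Cohen's d effect-size grids with star categories, reciprocal
    interval overlap with a length-preserving shuffle null, BLAST
    bitscore-based gene/TE homology classification, TPM and rescue/timing
    expression classifiers, and a synthetic-data generator that emulates
    pollen nuclei along a developmental trajectory so every stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
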