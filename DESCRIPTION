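Package: exoqc
Title: Post-Calling Quality Control and Validation for Exome Sequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Implements a post-variant-calling quality-control pipeline for
    family-based exome sequencing cohorts: per-sample metric screening with
    population-stratified MAD outlier removal, contamination policy and sex
    inference; PCA-based continental ancestry assignment against a labelled
    reference panel; array-identity, kinship and pedigree-consistency checks
    with sample-swap and duplicate resolution; random-forest variant quality
    scoring with percentile binning and an integrated variant-by-genotype
    filter grid evaluated by truth retention, trio transmission balance and
    truth-sample precision/recall; and downstream validation analyses
    (ultra-rare variant classification, high-confidence PTV calling, S_het
    burden scores, phenotype association, DNA-source comparisons and exact
    Poisson genetic-prevalence estimation). A fully labelled synthetic birth
    cohort generator with Mendelian trios, ancestry structure, an OxoG-style
    C>A batch artefact, contamination, swaps, duplicates and cell-line
    somatic excess provides ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
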