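Package: hblup
Title: Single-Step Genomic BLUP for Joint Analysis of Tree Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-step genomic evaluation (HBLUP) of
    multigenerational tree breeding populations. Builds pedigree numerator
    relationship matrices with inbreeding and race genetic groups, genomic
    relationship matrices (VanRaden method 1) with tuning and blending
    against the genotyped pedigree block, and the combined H matrix and its
    inverse. A sparse average-information REML engine fits individual-tree
    mixed models with region-specific additive variances and unstructured
    inter-region correlations, returning breeding values with exact
    prediction error variances and accuracies. Includes the two-stage
    analysis flow used in operational tree breeding (single-site spatial
    adjustment, per-trial standardization, multi-region fits), scenario
    comparison of pedigree-only and single-step models, pedigree-error
    detection from genomic versus expected relationships, and a gene-drop
    simulator of structured dual-program breeding populations for method
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
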