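Package: guildscan
Title: Guild-Structured Microbiome Analysis for Paired Two-Arm Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested reimplementation of a 16S rRNA
    amplicon analysis pipeline for paired (before/after) two-arm clinical
    cohorts: paired-end read quality control (end trimming, overlap merging,
    expected-error filtering), greedy 97% OTU clustering, rarefaction and
    alpha/beta diversity, PCA/PCoA ordination with MANOVA and a seeded
    PERMANOVA engine, SparCC basis-correlation estimation with bootstrap
    pseudo-p-values, co-abundance group (CAG) detection by Ward clustering
    with PERMANOVA-validated splits, CAG abundance quantification and
    network export, and clinical-endpoint statistics (HOMA indices, LOCF,
    paired tests, ANCOVA, Spearman CAG-clinical association grids). A
    synthetic-data module generates guild-structured compositional counts,
    paired cohorts with planted effects, FASTQ read pairs and random trees
    with known ground truth, so every stage is validated by recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
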