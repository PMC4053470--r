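Package: genometab
Title: Combined Genomic and Metabolomic Analysis of Urinary Albumin Excretion
Version: 0.1.0
Authors@R: person("INCLIVA", "Pipeline Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for joint genomic and serum-metabolomic
    analysis of microalbuminuria in population cohorts. Provides 1H-NMR
    spectrum preprocessing (alanine-doublet referencing, 0.01 ppm bucketing
    over the 0.50-4.70 ppm aliphatic window, total-area normalization and
    region reduction), metabolite quantification against a 26-region serum
    panel, PLS-DA discrimination of urinary-albumin-excretion status with
    10-fold Venetian-blind cross-validation, SNP quality control and
    genetic-model association with log urinary albumin excretion under
    Holm-Bonferroni correction, and a genotype-stratified metabolomic
    difference procedure that nominates risk and protective genotypes. A
    synthetic-cohort generator reproduces the statistical structure of such
    studies so the whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
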