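Package: gxelmm
Title: Mixed-Model Correction of Population Structure in Gene-by-Environment
    Genome-Wide Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide testing of SNP and gene-by-environment interaction
    (GEI) effects on quantitative traits with correction for population
    structure on both statistic families. Implements a linear mixed model
    with two random effects: one over the genetic relationship matrix K and
    one over a GxE kinship K^D that retains relatedness only between
    individuals sharing an environmental exposure (with kernels for
    continuous exposures). Variance components are estimated by
    average-information REML once per phenotype and reused for every
    variant's generalized-least-squares F-test. Includes readers and
    writers for PLINK and GCTA GRM formats, phenotype and genotype quality
    control, genomic-control inflation diagnostics, and a seeded
    two-population simulator of structured genotypes and null GxE
    phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
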