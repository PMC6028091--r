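Package: awmpcit
Title: Association Weight Matrix and PCIT Co-Association Networks for
    Multi-Trait GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A post-GWAS systems-biology toolkit for correlated
    quantitative traits. Provides a seeded simulator of multi-breed SNP
    panels, gene maps and correlated yield-deviation phenotypes with
    known truth; quality control (call rate, per-breed minor allele
    frequency, Hardy-Weinberg equilibrium); a genomic relationship
    matrix and single-SNP mixed-linear-model association with Bonferroni
    correction; construction of the Association Weight Matrix (AWM) of
    z-scored allele-substitution effects for pleiotropic SNP selected
    around a key trait; partial-correlation-and-information-theory
    (PCIT) filtering of SNP/gene co-association networks; and an
    orchestrated, reproducible end-to-end pipeline with standard-format
    export (VCF, BED, TSV, GraphML, JSON).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    igraph,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
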