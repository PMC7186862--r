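Package: crossmr
Title: Cross-Trait GWAS Look-Ups and Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for cross-phenotype analysis of GWAS summary statistics:
    a look-up pipeline that clusters genome-wide-significant anthropometric
    SNPs into independent loci (positional window plus linkage-disequilibrium
    splitting), tests them in mental-phenotype summary statistics under a
    Bonferroni threshold, selects lead SNPs and tabulates effect-direction
    concordance; and a two-sample Mendelian randomization suite with Wald
    ratios, inverse-variance-weighted and MR-Egger estimators, the robust
    adjusted profile score (simple and overdispersed), Cochran's Q
    heterogeneity, instrument-strength F statistics, single-SNP and
    leave-one-out sensitivity analyses, plot-data export, and a
    binary-outcome power calculator. A synthetic-data module generates
    summary-statistic studies with known causal effects, pleiotropy and
    planted look-up loci so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
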