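Package: genoconcord
Title: Cross-Platform Genotype Concordance Evaluation and Harmonization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-control toolkit for comparing genotype calls made on the
    same samples by two platforms (e.g. next-generation sequencing or
    imputation versus a SNP microarray). Matches variants by rs identifier,
    excludes allele-inconsistent sites, cross-classifies calls including
    missingness into a 4x4 table, computes per-SNP concordance rates
    conditional on the microarray call, tests for technology- and
    phenotype-differential concordance with Welch t-tests, stratifies
    discordance by minor allele frequency, and resolves discordant call pairs
    into allele dosages by 50-50 weighting. A simulation module generates
    paired call sets with known confusion-matrix error mechanisms,
    Hardy-Weinberg truth genotypes, and phenotype-linked (differential) error
    processes so every pipeline stage can be verified without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    yaml,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
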