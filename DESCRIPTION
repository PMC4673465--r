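Package: popdiffr
Title: Population Differentiation and Imputation Accuracy at Dense SNP Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genetic differentiation between closely
    related populations at dense SNP regions such as the MHC: SNP-level and
    multi-allelic haplotype-level F_ST estimation, population-structure
    analyses by genotype PCA and principal coordinates of F_ST distance
    matrices, gene-region haplotype cataloguing with major-haplotype
    dissimilarity statistics, a top-quantile F_ST enrichment test, and a
    Li-Stephens haplotype-copying imputation model with a masked-SNP
    accuracy protocol (discordance = 1 - r^2). Includes a multi-population
    synthetic data generator (Balding-Nichols allele frequencies plus
    founder-mosaic haplotypes) so the whole pipeline is testable without
    access restrictions on cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
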