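Package: admixrisk
Title: Comparative Polygenic Risk Analysis for Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing unweighted polygenic risk between admixed
    population samples: GWAS-catalog filtering to lead risk SNPs, per-SNP
    risk-allele log odds ratios with fixed- and random-effects meta-analysis,
    bootstrap and random-SNP-set null controls, a multi-disease risk-score
    bias scan, supervised ancestry-fraction estimation, and ancestry-risk
    regression. Includes a Balding-Nichols admixture simulator that generates
    genotype, truth and catalog inputs with known ground truth, so the whole
    pipeline can be exercised end-to-end without external data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
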