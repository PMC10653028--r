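Package: meripdm
Title: Differential m6A Methylation Analysis for MeRIP-seq with
    Expression-Confounding Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for differential N6-methyladenosine
    (m6A) epitranscriptome analysis from MeRIP-seq count data.  Implements
    negative-binomial generalized linear models on paired IP/input counts,
    a three-test consensus for differential methylation, correction of
    methylation fold changes for underlying differential gene expression,
    a lightweight Poisson window peak caller with transcript-feature
    annotation, candidate integration with hypergeometric gene-set
    over-representation and deterministic ranking, bench-validation
    calculators (RT-qPCR relative expression, MeRIP/RIP-qPCR enrichment,
    drug-interaction synergy, actinomycin-D half-life), and a synthetic
    MeRIP-seq generator with planted ground truth so every stage can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
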