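Package: triohet
Title: Trio Transcriptome Analysis of Heterosis in Hybrids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gene expression and alternative splicing in a
    trio design (hybrid plus its two parents), as used in studies of heterosis
    in interspecies crosses such as mules and hinnies. Provides a self-contained
    negative-binomial differential-expression test, percent-spliced-in (PSI)
    differential-splicing tests, classification of genes and splicing events
    into gene-action modes (additive, high-/low-parent dominance, over-/
    under-dominance), long-read intron-chain validation of splicing calls,
    hypergeometric gene-set enrichment, sample-correlation clustering, and a
    synthetic-data generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
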