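Package: xenocall
Title: Kmer-Level Models and Basecalling for Expanded-Alphabet (XNA) Nanopore Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting synthetic xenonucleotides (XNAs) in nanopore
    sequencing data from segmented, normalized current-level tables. Provides a
    12-letter expanded DNA alphabet with pairing and canonical-substitution
    rules, 4-nt kmer current-level model fitting (mean, median, or kernel
    density estimate), per-read and consensus basecalling by log-likelihood
    ratio (LLR) and outlier-robust LLR (ORLLR) hypothesis tests, recall /
    specificity / ROC benchmarking, Monte-Carlo read simulation from any kmer
    model, and design of the barcoded hairpin libraries and ground-truth
    reference sets that kmer-model building depends on.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
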