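Package: biradsfusion
Title: Structured Reporting and Dual-Stream Fusion Classification for Breast MRI Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning free-text breast MRI reports into a fixed
    ten-category structured template with "not mentioned" completion of missing
    categories, building knowledge-driven few-shot prompts for an (optional)
    large-language-model structuring backend, and classifying reports into
    BI-RADS follow-up versus biopsy recommendations with a dual-stream
    transformer encoder fitted from scratch. Attention projections carry
    low-rank adaptation (LoRA) updates over a frozen base; the two report
    streams (free text and structured) are combined by one of five fusion
    strategies before a softmax head. Includes a synthetic paired-report
    generator with controllable per-category missingness and label-linked
    personal-history clauses, a BERTScore implementation for grading
    structuring quality, classification metrics, and a seeded ablation
    harness. The training loop is implemented in C++ via RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
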