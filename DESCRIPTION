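Package: condrel
Title: Conditional Reliability at the Cut Score in Classical Test Theory and
    Item Response Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the measurement precision of pass-fail
    decisions in multiple-choice exams under Classical Test Theory (CTT) and
    Item Response Theory (IRT). Implements the binomial-error conditional
    standard error of measurement and its Raju-style standardisation into a
    conditional reliability curve, a one-parameter logistic partial credit
    model estimated by marginal maximum likelihood (EM over normal
    quadrature), Warm's weighted likelihood ability estimation, test
    information and the IRT conditional reliability curve, local-independence
    (Q3) and item-fit (infit/outfit, SRMR/SRMSR) diagnostics, per-exam
    cut-score reports, and study-level comparisons (paired ANOVA and a
    stacked interaction regression of influencing factors). A synthetic-exam
    generator emulates cohorts of mixed single-best-answer and multiple
    true-false exams with partial-credit scoring and year-linked range
    restriction, so the full pipeline is testable without access to real
    exam data.
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
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
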