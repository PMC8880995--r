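Package: dicoverge
Title: Inter-Tissue Divergence-Convergence Analysis of Lifespan Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for asking whether tissues of the same
    individual become transcriptionally more similar or more different with
    age. Implements per-gene expression-age trajectories split into
    developmental and ageing periods, up-down/down-up expression-reversal
    classification, the inter-tissue coefficient-of-variation (CoV)
    divergence-convergence ("DiCo") statistic with dependence-preserving
    permutation tests, jackknife ratio ranges, effect-size-based
    tissue-specificity calling with identity-loss contingency tests,
    heteroscedasticity checks, and signature-regression deconvolution of bulk
    profiles into cell-type contributions. A synthetic multi-tissue lifespan
    data generator with planted gene classes makes every stage testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    yaml
Suggests:
    car,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
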