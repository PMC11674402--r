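Package: fcbench
Title: Statistical Benchmarks for Individual Functional Connectivity
    Predictions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Statistical evaluation of whether predicted functional
    connectivity matrices capture individual-specific effects beyond
    group-average and noise benchmarks. Implements intra- versus
    inter-individual similarity testing on cross-subject similarity
    matrices (naive one-sample t, fold-constrained permutation, and the
    corrected resampled t-test for cross-validated predictions),
    fold-respecting group-mean and matched-noise benchmark predictions,
    fold-respecting standardization, Pearson and log-Euclidean Riemannian
    similarity between connectivity matrices, Hungarian-assignment subject
    matching curves with FDR control, and a synthetic cohort simulator
    with known group/individual covariance structure for calibration and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
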