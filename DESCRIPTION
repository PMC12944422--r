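Package: thermocal
Title: Agreement Analysis and Machine-Learning Calibration for Paired Thermometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for method-comparison studies of paired temperature
    instruments: intra-participant precision, paired and one-sample t-tests,
    Bland-Altman bias and 95% limits of agreement, ICC(2,1) absolute-agreement
    reliability, and Pearson correlation, plus a ten-model calibration suite
    (robust polynomial, Deming, isotonic, Huber splines, LOESS, weighted
    splines, quantile and monotone gradient boosting, random forest, extra
    trees) evaluated with leakage-free participant-grouped cross-validation
    and 95% quantile or split-conformal prediction intervals. Includes a
    synthetic study generator that reproduces the measurement structure of a
    two-round, two-device repeated-measures design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    splines,
    stats,
    utils,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
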