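Package: grsrecal
Title: Recalibration of Absolute Cancer Risk Models Augmented with
    Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adding a weighted genetic risk score (GRS) to
    previously validated absolute risk prediction models for colorectal
    cancer, recalibrating the combined models with flexible parametric
    (Royston-Parmar) survival models on the log cumulative hazard scale,
    and evaluating calibration, discrimination and change in individual
    predicted risk. Includes a synthetic cohort generator (Hardy-Weinberg
    genotypes, lifestyle covariates, family history weakly linked to the
    GRS, Weibull proportional-hazards event times, sibling pairs, and
    optional winner's-curse inflation of published SNP weights), KING-style
    kinship estimation with greedy relatedness filtering, Harrell's
    C-statistic, decile calibration against Kaplan-Meier estimates, and
    relative-risk calibration curves.
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
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
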