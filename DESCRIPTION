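Package: grfstep
Title: Gait-Cycle Segmentation and Loading-Condition Classification from
    Insole Ground Reaction Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for turning continuous three-region (heel, midfoot,
    forefoot) insole ground-reaction-force recordings into step-level
    activity classifications. Provides a gait-cycle parser combining
    signal-intersection and force-peak detection, a large parameterised
    time-series feature bank, two-stage feature selection (correlated-group
    pruning by single-feature model performance, then top-K ANOVA F-score
    with the one-standard-error rule over cross-validation), per-subject
    Random Forest classification of walking speed and treadmill incline
    with top-k evaluation, and a synthetic gait simulator with exported
    ground-truth events for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
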