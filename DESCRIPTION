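Package: leaktraj
Title: Postoperative Biomarker Trajectories for Predicting Anastomotic Leak
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 5-day postoperative trajectories of
    procalcitonin (PCT), C-reactive protein (CRP) and white-blood-cell
    count (WBC) as predictors of anastomotic leak after colorectal
    surgery. Provides a synthetic cohort simulator parameterised by
    group-wise means and standard deviations, per-patient trajectory
    statistics (least-squares slopes, consecutive-day deltas, threshold
    rise rules), logistic models with ROC/AUC evaluation (DeLong
    inference, Youden-index cutoffs, confusion metrics), intra-individual
    variability indices (within-subject SD, CV and variability
    independent of the mean with a fitted power-law exponent),
    finite-population sample-size arithmetic, and an end-to-end
    reproducible reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
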