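# ROC machinery: concordance AUC vs brute-force and trapezoid, DeLong
# inference, Youden cutoffs and confusion metrics.

test_that("concordance AUC matches exhaustive pair enumeration", {
  # 6 class pairs: 5 wins + 1 half-tie
  expect_equal(roc_auc(c(1, 2, 3, 3, 4), c(0, 0, 1, 0, 1)), 11 / 12)

  set.seed(101)
  for (i in 1:200) {
    f <- random_roc_fixture()
    a <- roc_auc(f$scores, f$labels)
    expect_equal(a, brute_force_auc(f$scores, f$labels))
    # and equals the trapezoidal area under the ROC curve
    curve <- roc_curve(f$scores, f$labels)
    trap <- sum(diff(curve$fpr) *
                  (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
    expect_equal(a, trap, tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(103)
  for (i in 1:25) {
    f <- random_roc_fixture()
    curve <- roc_curve(f$scores, f$labels)
    expect_equal(c(curve$fpr[1], curve$tpr[1]), c(0, 0))
    expect_equal(c(curve$fpr[nrow(curve)], curve$tpr[nrow(curve)]), c(1, 1))
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
  }
})

test_that("AUC is invariant under increasing transforms, flips with labels", {
  set.seed(107)
  f <- random_roc_fixture(25)
  a <- roc_auc(f$scores, f$labels)
  expect_equal(roc_auc(exp(f$scores), f$labels), a)
  expect_equal(roc_auc(3 * f$scores - 7, f$labels), a)
  expect_equal(roc_auc(f$scores, 1 - f$labels), 1 - a)
  # degenerate inputs are rejected
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), class = "leaktraj_data_error")
})

test_that("separated and uninformative scores give AUC 1 and 0.5", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1)), 0.5)
})

test_that("DeLong inference brackets the AUC and tests against chance", {
  # identical score distributions in the two groups: AUC exactly 0.5, p = 1
  inf <- auc_inference(c(1, 2, 3, 1, 2, 3), c(0, 0, 0, 1, 1, 1))
  expect_equal(inf$auc, 0.5)
  expect_equal(inf$p_value, 1)

  set.seed(109)
  f <- random_roc_fixture(30)
  inf <- auc_inference(f$scores, f$labels)
  expect_lte(inf$ci_low, inf$auc)
  expect_gte(inf$ci_high, inf$auc)
  expect_gte(inf$ci_low, 0)
  expect_lte(inf$ci_high, 1)

  # CI width shrinks as the sample grows at fixed signal
  set.seed(113)
  widths <- sapply(c(50, 200, 800), function(n) {
    labels <- rep(0:1, each = n / 2)
    scores <- rnorm(n, mean = labels)
    ci <- auc_inference(scores, labels)
    ci$ci_high - ci$ci_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("DeLong interval agrees with pROC and a bootstrap on a fixture", {
  set.seed(127)
  labels <- rep(c(0, 1), c(20, 10))
  scores <- rnorm(30, mean = 1.2 * labels)
  inf <- auc_inference(scores, labels)

  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(inf$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(inf$auc, as.numeric(ref[2]), tolerance = 1e-8)
  expect_equal(inf$ci_high, as.numeric(ref[3]), tolerance = 1e-8)

  # stratified bootstrap as a second, assumption-free route
  boots <- replicate(2000, {
    i1 <- sample(which(labels == 1), replace = TRUE)
    i0 <- sample(which(labels == 0), replace = TRUE)
    roc_auc(scores[c(i0, i1)], labels[c(i0, i1)])
  })
  bq <- quantile(boots, c(0.025, 0.975))
  expect_lt(abs(inf$ci_low - bq[[1]]), 0.05)
  expect_lt(abs(inf$ci_high - bq[[2]]), 0.05)

  # Hanley-McNeil cross-check is close to DeLong here
  hm <- auc_inference(scores, labels, method = "hanley")
  expect_equal(hm$auc, inf$auc)
  expect_lt(abs(hm$se - inf$se), 0.03)
})

test_that("Youden cutoff equals the exhaustive-scan maximizer", {
  oc <- optimal_cutoff(c(0.1, 0.2, 0.6, 0.7), c(0, 0, 1, 1))
  expect_gt(oc$cutoff, 0.2)
  expect_lt(oc$cutoff, 0.6)
  expect_equal(unclass(oc$table)[c("tp", "fp", "fn", "tn")],
               list(tp = 2, fp = 0, fn = 0, tn = 2))
  expect_equal(oc$youden, 1)

  set.seed(131)
  for (i in 1:200) {
    f <- random_roc_fixture()
    oc <- optimal_cutoff(f$scores, f$labels)
    expect_equal(oc$youden, brute_force_best_j(f$scores, f$labels),
                 tolerance = 1e-12)
    # the reported confusion table is the one induced by the cutoff
    pred <- f$scores >= oc$cutoff
    expect_equal(oc$table$tp, sum(pred & f$labels == 1))
    expect_equal(oc$table$tn, sum(!pred & f$labels == 0))
  }
})

test_that("J-ties break toward the higher-specificity cutoff", {
  # both "everything positive" rules J = 0; also any cutoff here gives J = 0
  scores <- c(1, 2, 1, 2)
  labels <- c(0, 1, 1, 0)
  oc <- optimal_cutoff(scores, labels)
  # highest candidate cutoff wins: everything negative, SP = 100%
  expect_gt(oc$cutoff, 2)
  expect_equal(confusion_metrics(oc$table)$sp, 100)
})

test_that("confusion metrics reproduce the standard formulas", {
  m <- confusion_metrics(confusion_table(tp = 17, fp = 6, fn = 5, tn = 177))
  expect_equal(round_half_up(m$sn, 1), 77.3)
  expect_equal(round_half_up(m$sp, 1), 96.7)
  expect_equal(round_half_up(m$ppv, 1), 73.9)
  expect_equal(round_half_up(m$npv, 1), 97.3)

  perfect <- confusion_metrics(confusion_table(22, 0, 0, 183))
  expect_equal(unlist(perfect), c(sn = 100, sp = 100, ppv = 100, npv = 100))

  allneg <- confusion_metrics(confusion_table(0, 0, 22, 183))
  expect_equal(allneg$sn, 0)
  expect_equal(allneg$sp, 100)
  expect_equal(round_half_up(allneg$npv, 1), 89.3)
  expect_true(is.na(allneg$ppv))  # zero denominator: marker, not an error
})

test_that("binary predictors are summarised by their 2x2 table", {
  flag <- c(1, 1, 0, 0, 1, 0, 0, 0)
  labels <- c(1, 1, 1, 0, 0, 0, 0, 0)
  row <- summarise_roc(flag, labels, name = "rule", binary = TRUE)
  expect_equal(row$sn, 100 * 2 / 3)
  expect_equal(row$sp, 100 * 4 / 5)
  # AUC of a binary test is the single-point ROC area (SN + SP) / 2
  expect_equal(row$auc, (2 / 3 + 4 / 5) / 2)
  expect_true(is.na(row$cutoff))
})
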