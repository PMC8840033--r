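# ROC machinery: concordance AUC, ROC curve construction, DeLong and
# Hanley-McNeil inference, Youden-index cutoffs and confusion metrics.

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) abort_data("labels must be 0/1")
  if (length(unique(labels)) < 2) {
    abort_data("both outcome classes must be present")
  }
}

#' Area under the ROC curve by pairwise concordance
#'
#' The probability that a randomly chosen case (label 1) scores higher than
#' a randomly chosen control (label 0), with ties counted one half —
#' computed from midranks, equivalent to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores Numeric prediction scores (higher = more likely a case).
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_two_classes(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (predict case when
#' `score >= threshold`), from (0, 0) to (1, 1).
#'
#' @inheritParams roc_auc
#' @return A tibble with columns `threshold`, `tpr` (sensitivity) and `fpr`
#'   (1 - specificity), ordered by increasing `fpr`.
#' @export
roc_curve <- function(scores, labels) {
  check_two_classes(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  last <- !duplicated(s, fromLast = TRUE)   # last index of each distinct score
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp / sum(labels == 1)),
    fpr = c(0, fp / sum(labels == 0))
  )
}

# trapezoidal area under a roc_curve tibble
trapezoid_area <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# DeLong components: placement values and their variances
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x)
  n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  list(
    auc = mean(psi),
    var = stats::var(v10) / m + stats::var(v01) / n
  )
}

#' Confidence interval and test versus chance for an AUC
#'
#' 95% (or other level) confidence interval and a two-sided p-value against
#' the chance value AUC = 0.5 (the ROC diagonal). The default variance
#' estimator is DeLong's; Hanley-McNeil is available for cross-checking.
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"hanley"`.
#' @return A list with `auc`, `se`, `ci_low`, `ci_high` (truncated to
#'   `[0, 1]`) and `p_value`.
#' @export
auc_inference <- function(scores, labels, level = 0.95,
                          method = c("delong", "hanley")) {
  method <- match.arg(method)
  check_two_classes(labels)
  if (method == "delong") {
    comp <- delong_components(scores, labels)
    a <- comp$auc
    v <- comp$var
  } else {
    a <- roc_auc(scores, labels)
    m <- sum(labels == 1)
    n <- sum(labels == 0)
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    v <- (a * (1 - a) + (m - 1) * (q1 - a^2) + (n - 1) * (q2 - a^2)) / (m * n)
  }
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    if (abs(a - 0.5) < .Machine$double.eps^0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs(a - 0.5) / se)
  }
  list(
    auc = a,
    se = se,
    ci_low = max(0, a - z * se),
    ci_high = min(1, a + z * se),
    p_value = p
  )
}

#' Build a confusion table
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) abort_data("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_table")
}

#' Sensitivity, specificity and predictive values
#'
#' All four metrics on the percentage (0-100) scale:
#' SN = TP/(TP+FN), SP = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN).
#' A metric whose denominator is zero is returned as `NA` rather than
#' raising an error. Predictive values are at the sample prevalence.
#'
#' @param tab A [confusion_table()].
#' @return Named list `sn`, `sp`, `ppv`, `npv` (percent, unrounded).
#' @export
confusion_metrics <- function(tab) {
  stopifnot(inherits(tab, "confusion_table"))
  frac <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(
    sn = frac(tab$tp, tab$tp + tab$fn),
    sp = frac(tab$tn, tab$tn + tab$fp),
    ppv = frac(tab$tp, tab$tp + tab$fp),
    npv = frac(tab$tn, tab$tn + tab$fn)
  )
}

#' Youden-index optimal cutoff
#'
#' Scans candidate thresholds (midpoints between adjacent distinct scores,
#' plus one below the minimum and one above the maximum) and returns the
#' cutoff maximizing Youden's J = sensitivity + specificity - 1, with a
#' patient predicted positive when `score >= cutoff`. Ties in J are broken
#' toward the higher cutoff, i.e. toward higher specificity.
#'
#' @inheritParams roc_auc
#' @return A list with `cutoff`, `youden` (J at the cutoff) and `table`
#'   (the [confusion_table()] at the cutoff).
#' @export
optimal_cutoff <- function(scores, labels) {
  check_two_classes(labels)
  s <- sort(unique(scores))
  candidates <- c(
    s[1] - 1,
    if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
    s[length(s)] + 1
  )
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  best <- NULL
  for (cut in candidates) {
    pred <- scores >= cut
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    j <- tp / n1 + (n0 - fp) / n0 - 1
    if (is.null(best) || j > best$youden + 1e-12 ||
        (abs(j - best$youden) <= 1e-12 && cut > best$cutoff)) {
      best <- list(
        cutoff = cut,
        youden = j,
        table = confusion_table(tp, fp, n1 - tp, n0 - fp)
      )
    }
  }
  best
}

#' Summarise the predictive performance of a score
#'
#' Bundles the full ROC summary for one predictor: AUC with confidence
#' interval and p-value versus chance, the Youden-optimal cutoff and the
#' confusion metrics at that cutoff. For a binary predictor (0/1 flag) the
#' 2x2 table at `flag == 1` is used directly, its AUC being the single-point
#' ROC area (SN + SP)/2, and no cutoff is reported.
#'
#' @inheritParams roc_auc
#' @param name Label for the summary row.
#' @param binary Treat `scores` as a 0/1 classification flag.
#' @param level Confidence level for the AUC interval.
#' @return A one-row tibble: `model`, `n`, `n_pos`, `auc`, `ci_low`,
#'   `ci_high`, `p_value`, `cutoff`, `sn`, `sp`, `ppv`, `npv` (percent).
#' @export
summarise_roc <- function(scores, labels, name = "score", binary = FALSE,
                          level = 0.95) {
  check_two_classes(labels)
  inf <- auc_inference(scores, labels, level = level)
  if (binary) {
    tab <- confusion_table(
      tp = sum(scores == 1 & labels == 1),
      fp = sum(scores == 1 & labels == 0),
      fn = sum(scores == 0 & labels == 1),
      tn = sum(scores == 0 & labels == 0)
    )
    cutoff <- NA_real_
  } else {
    oc <- optimal_cutoff(scores, labels)
    tab <- oc$table
    cutoff <- oc$cutoff
  }
  met <- confusion_metrics(tab)
  tibble::tibble(
    model = name,
    n = length(labels),
    n_pos = sum(labels == 1),
    auc = inf$auc,
    ci_low = inf$ci_low,
    ci_high = inf$ci_high,
    p_value = inf$p_value,
    cutoff = cutoff,
    sn = met$sn,
    sp = met$sp,
    ppv = met$ppv,
    npv = met$npv
  )
}
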