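# Intra-individual (visit-to-visit) variability: within-subject SD and CV,
# and variability independent of the mean (VIM) with its power-law exponent
# fitted across patients.

#' Within-subject summary statistics
#'
#' Sample mean, sample SD (n - 1 denominator) and coefficient of variation
#' (SD / mean) of one patient's repeated measurements.
#'
#' @param values Numeric vector of one patient's measurements (>= 2).
#' @return A list with `within_mean`, `within_sd`, `cv` (`cv` is `NA` when
#'   the mean is 0).
#' @export
within_subject_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort_data("need at least 2 measurements for within-subject statistics")
  }
  m <- mean(values)
  s <- stats::sd(values)
  list(
    within_mean = m,
    within_sd = s,
    cv = if (m == 0) NA_real_ else s / m
  )
}

#' Fit the SD-versus-mean power law
#'
#' Nonlinear least squares for `SD = a * mean^x` across patients,
#' initialized from an ordinary least-squares fit of `log(SD)` on
#' `log(mean)` over the points with positive SD. The exponent `x` is what
#' VIM uses to remove the mean dependence of the within-subject SD.
#'
#' @param means Per-patient within-subject means (> 0, not all equal).
#' @param sds Per-patient within-subject SDs (>= 0).
#' @return A list of class `power_law_fit`: `a`, `x`, `n_points`, `rss`,
#'   `converged`.
#' @export
fit_power_law <- function(means, sds) {
  keep <- !is.na(means) & !is.na(sds) & means > 0
  means <- means[keep]
  sds <- sds[keep]
  if (length(means) < 3) abort_data("need >= 3 (mean, sd) points")
  if (length(unique(means)) < 2) abort_data("all means identical")

  pos <- sds > 0
  if (sum(pos) >= 2 && length(unique(means[pos])) >= 2) {
    init <- stats::lm(log(sds[pos]) ~ log(means[pos]))
    start <- list(a = exp(stats::coef(init)[[1]]), x = stats::coef(init)[[2]])
  } else {
    start <- list(a = mean(sds), x = 0)
  }
  fit <- minpack.lm::nls.lm(
    par = c(a = start$a, x = start$x),
    fn = function(par) sds - par[1] * means^par[2],
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
  )
  est <- fit$par
  structure(
    list(
      a = est[["a"]],
      x = est[["x"]],
      n_points = length(means),
      rss = fit$deviance,
      converged = fit$info %in% 1:4
    ),
    class = "power_law_fit"
  )
}

#' Variability independent of the mean
#'
#' `VIM = within_sd / within_mean^x * cohort_mean^x`: the within-subject SD
#' rescaled so that its power-law dependence on the subject's own mean is
#' removed, expressed in marker units at the cohort-average level.
#'
#' @param within_sd,within_mean Per-patient within-subject SD and mean
#'   (`within_mean > 0`).
#' @param x Power-law exponent (from [fit_power_law()]).
#' @param cohort_mean Mean of the marker over all included measurements in
#'   the cohort.
#' @return VIM in marker units (`NA` where `within_mean <= 0`).
#' @export
vim <- function(within_sd, within_mean, x, cohort_mean) {
  out <- within_sd / within_mean^x * cohort_mean^x
  out[within_mean <= 0] <- NA_real_
  out
}

#' Per-patient variability indices for a cohort
#'
#' For each marker: within-subject mean, SD and CV per patient, the pooled
#' (both outcome groups) power-law fit `SD = a * mean^x`, and VIM. Patients
#' contribute only with at least `min_points` measurements in the window
#' (default 3 — an SD from 2 points is legal but very noisy).
#'
#' @inheritParams trajectory_features
#' @param min_points Minimum measurements per patient to contribute.
#' @return A tibble with one row per (patient, marker): `patient_id`,
#'   `al_label`, `marker`, `n_obs`, `within_mean`, `within_sd`, `cv`,
#'   `vim`. The per-marker power-law fits are attached as the
#'   `"power_fits"` attribute (tibble: `marker`, `a`, `x`, `cohort_mean`).
#' @export
variability_indices <- function(cohort, window = "0-5", min_points = 3) {
  cohort <- apply_window(cohort, window)
  per_patient <- cohort |>
    dplyr::group_by(.data$patient_id, .data$al_label, .data$marker) |>
    dplyr::filter(dplyr::n() >= min_points) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      within_mean = mean(.data$value),
      within_sd = stats::sd(.data$value),
      .groups = "drop"
    )
  per_patient$cv <- ifelse(
    per_patient$within_mean == 0, NA_real_,
    per_patient$within_sd / per_patient$within_mean
  )

  fits <- lapply(split(per_patient, per_patient$marker), function(d) {
    fit <- fit_power_law(d$within_mean, d$within_sd)
    cm <- mean(cohort$value[cohort$marker == d$marker[1]])
    tibble::tibble(marker = d$marker[1], a = fit$a, x = fit$x,
                   cohort_mean = cm)
  })
  fits <- dplyr::bind_rows(fits)

  per_patient <- dplyr::left_join(per_patient, fits, by = "marker")
  per_patient$vim <- vim(per_patient$within_sd, per_patient$within_mean,
                         per_patient$x, per_patient$cohort_mean)
  out <- per_patient[, c("patient_id", "al_label", "marker", "n_obs",
                         "within_mean", "within_sd", "cv", "vim")]
  attr(out, "power_fits") <- fits
  out
}

#' Compare an index between outcome groups
#'
#' Group means, the mean difference with a Welch-type 95% confidence
#' interval, the Mann-Whitney U statistic (cross-group wins plus half-ties,
#' leak group first) and its tie-corrected normal-approximation p-value.
#'
#' @param values Numeric index values.
#' @param labels 0/1 outcome labels (1 = leak).
#' @param level Confidence level for the mean-difference interval.
#' @return A one-row tibble: `mean_no_al`, `mean_al`, `diff`, `ci_low`,
#'   `ci_high`, `u_stat`, `p_value`.
#' @export
compare_groups <- function(values, labels, level = 0.95) {
  check_two_classes(labels)
  keep <- !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  g1 <- values[labels == 1]
  g0 <- values[labels == 0]
  if (length(g1) == 0 || length(g0) == 0) abort_data("empty outcome group")
  tt <- stats::t.test(g1, g0, conf.level = level)
  wt <- suppressWarnings(
    stats::wilcox.test(g1, g0, exact = FALSE, correct = FALSE)
  )
  tibble::tibble(
    mean_no_al = mean(g0),
    mean_al = mean(g1),
    diff = mean(g1) - mean(g0),
    ci_low = tt$conf.int[1],
    ci_high = tt$conf.int[2],
    u_stat = unname(wt$statistic),
    p_value = wt$p.value
  )
}

#' Group comparison of all variability indices
#'
#' One [compare_groups()] row per (marker, index) for the within-subject
#' SD, CV and VIM.
#'
#' @param indices Output of [variability_indices()].
#' @return A tibble with columns `marker`, `index` and the comparison
#'   columns.
#' @export
variability_comparison <- function(indices) {
  long <- tidyr::pivot_longer(
    indices[, c("patient_id", "al_label", "marker",
                "within_sd", "cv", "vim")],
    cols = c("within_sd", "cv", "vim"),
    names_to = "index", values_to = "value"
  )
  long$index <- c(within_sd = "SD", cv = "CV", vim = "VIM")[long$index]
  long |>
    dplyr::group_by(.data$marker, .data$index) |>
    dplyr::reframe(compare_groups(.data$value, .data$al_label)) |>
    dplyr::arrange(.data$marker, match(.data$index, c("SD", "CV", "VIM")))
}
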