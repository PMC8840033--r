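# Per-patient trajectory statistics: least-squares slopes over the
# observation window, consecutive-day differences, and threshold rise rules.

#' Least-squares trend of a marker over the observation window
#'
#' Ordinary least-squares slope of value on day index — the "average linear
#' trend" of a biomarker over its measurement schedule, in marker units per
#' day.
#'
#' @param days Day indices (distinct, at least two).
#' @param values Marker values at those days.
#' @return The OLS slope (units/day).
#' @export
fit_linear_trend <- function(days, values) {
  keep <- !is.na(values) & !is.na(days)
  days <- days[keep]
  values <- values[keep]
  if (length(days) < 2) abort_data("need at least 2 observations for a trend")
  if (length(unique(days)) < 2) abort_data("all day indices identical")
  dc <- days - mean(days)
  sum(dc * (values - mean(values))) / sum(dc^2)
}

#' Differences between consecutive scheduled days
#'
#' Value changes between adjacent days of the marker's schedule, in order.
#' For WBC (measured on days 0, 1, 3, 5) the pairs are 0->1, 1->3 and 3->5;
#' unmeasured days are never interpolated.
#'
#' @inheritParams fit_linear_trend
#' @return A tibble with columns `from_day`, `to_day`, `delta`.
#' @export
consecutive_deltas <- function(days, values) {
  if (length(days) < 2) abort_data("need at least 2 observations for deltas")
  o <- order(days)
  days <- days[o]
  values <- values[o]
  tibble::tibble(
    from_day = days[-length(days)],
    to_day = days[-1],
    delta = diff(values)
  )
}

#' Default rise-rule thresholds
#'
#' Marker-specific thresholds for a between-consecutive-day increase:
#' 50 mg/L for CRP, 0.5 ng/mL for PCT and 1.0 x1000/mm3 for WBC.
#'
#' @return A named numeric vector of thresholds in marker units.
#' @export
default_rise_rules <- function() {
  c(CRP = 50, PCT = 0.5, WBC = 1.0)
}

#' Apply a rise rule to consecutive-day deltas
#'
#' A delta triggers when it strictly exceeds the marker's threshold ("more
#' than" the stated increase); a delta exactly equal to the threshold does
#' not. The any-pair flag is the OR over per-pair flags.
#'
#' @param deltas Numeric vector of consecutive-day differences.
#' @param threshold Positive rise threshold in marker units.
#' @return A list with `flag_any` (logical scalar) and `flags` (per-pair
#'   logical vector).
#' @export
apply_rise_rule <- function(deltas, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    abort_config("rise threshold must be a single positive number")
  }
  flags <- deltas > threshold
  list(flag_any = any(flags), flags = flags)
}

# restrict a cohort to the requested observation window
apply_window <- function(cohort, window = c("0-5", "1-5")) {
  window <- match.arg(window)
  if (window == "1-5") cohort <- cohort[cohort$day >= 1, ]
  cohort
}

#' Per-patient trajectory features for a whole cohort
#'
#' Computes, for every (patient, marker), the least-squares slope over the
#' observation window and the rise-rule flag over all consecutive-day pairs.
#'
#' @param cohort A cohort tibble (see [simulate_cohort()]).
#' @param window `"0-5"` to include the preoperative draw (default) or
#'   `"1-5"` to restrict to postoperative days.
#' @param rules Named vector of rise thresholds, as [default_rise_rules()].
#' @return A tibble with one row per (patient, marker): `patient_id`,
#'   `al_label`, `marker`, `n_obs`, `slope`, `rule_flag_any`.
#' @export
trajectory_features <- function(cohort, window = "0-5",
                                rules = default_rise_rules()) {
  cohort <- apply_window(cohort, window)
  missing_rules <- setdiff(unique(cohort$marker), names(rules))
  if (length(missing_rules) > 0) {
    abort_config(paste(
      "no rise threshold for marker:", paste(missing_rules, collapse = ", ")
    ))
  }
  cohort |>
    dplyr::group_by(.data$patient_id, .data$al_label, .data$marker) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      slope = fit_linear_trend(.data$day, .data$value),
      rule_flag_any = apply_rise_rule(
        consecutive_deltas(.data$day, .data$value)$delta,
        rules[[.data$marker[1]]]
      )$flag_any,
      .groups = "drop"
    )
}

#' Consecutive-day deltas and per-pair rule flags for a whole cohort
#'
#' @inheritParams trajectory_features
#' @return A tibble with one row per (patient, marker, day pair):
#'   `patient_id`, `al_label`, `marker`, `from_day`, `to_day`, `delta`,
#'   `rule_flag`.
#' @export
delta_table <- function(cohort, window = "0-5",
                        rules = default_rise_rules()) {
  cohort <- apply_window(cohort, window)
  cohort |>
    dplyr::group_by(.data$patient_id, .data$al_label, .data$marker) |>
    dplyr::reframe({
      d <- consecutive_deltas(.data$day, .data$value)
      d$rule_flag <- apply_rise_rule(d$delta, rules[[.data$marker[1]]])$flags
      d
    })
}
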