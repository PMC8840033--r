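# Panel evaluation: one ROC summary row per requested model — raw
# single-day values, trajectory slopes and their combinations, and binary
# rise rules.

# patient-level outcome, one row per patient, ordered by id
patient_outcomes <- function(cohort) {
  out <- unique(cohort[, c("patient_id", "al_label")])
  out[order(out$patient_id), ]
}

# wide matrix of slopes: rows = patients (sorted), one column per marker
slope_matrix <- function(features, markers) {
  wide <- tidyr::pivot_wider(
    features[, c("patient_id", "marker", "slope")],
    names_from = "marker", values_from = "slope"
  )
  wide <- wide[order(wide$patient_id), ]
  as.matrix(wide[, markers, drop = FALSE])
}

#' Model specifications for panel evaluation
#'
#' Helpers describing the three model families evaluated by
#' [evaluate_marker_panel()]: the raw marker value at a single day, a
#' logistic model on one or more trajectory slopes, and a binary
#' consecutive-day rise rule (over all day pairs or one specific pair).
#'
#' @param marker Marker name (`"CRP"`, `"PCT"`, `"WBC"`).
#' @param day Day index for a raw-value model.
#' @param markers Character vector of markers whose slopes enter a
#'   trajectory model.
#' @param from_day,to_day Restrict a rule model to one consecutive pair;
#'   both `NULL` (default) means "between any two consecutive days".
#' @return A model-spec list consumed by [evaluate_marker_panel()].
#' @export
raw_model <- function(marker, day) {
  list(type = "raw", marker = marker, day = day,
       name = sprintf("%s POD%d", marker, day))
}

#' @rdname raw_model
#' @export
trajectory_model <- function(markers) {
  list(type = "trajectory", markers = markers,
       name = paste0(paste(markers, collapse = "+"), " trajectory"))
}

#' @rdname raw_model
#' @export
rule_model <- function(marker, from_day = NULL, to_day = NULL) {
  pair <- if (is.null(from_day)) "any 2 days" else {
    sprintf("POD%d to POD%d", from_day, to_day)
  }
  list(type = "rule", marker = marker, from_day = from_day, to_day = to_day,
       name = sprintf("%s rise, %s", marker, pair))
}

#' Default model panel
#'
#' The full set of models reported by the study: every raw marker value at
#' its scheduled postoperative days, the three single trajectories and all
#' their pairwise and triple combinations, and each rise rule (any pair and
#' each consecutive pair).
#'
#' @return A list of model specs.
#' @export
default_model_panel <- function() {
  sched <- marker_schedule()
  raw <- unlist(lapply(seq_len(nrow(sched)), function(i) {
    days <- setdiff(sched$days[[i]], 0)
    lapply(days, function(d) raw_model(sched$marker[i], d))
  }), recursive = FALSE)
  traj <- lapply(
    list("CRP", "PCT", "WBC", c("PCT", "CRP"), c("PCT", "WBC"),
         c("CRP", "WBC"), c("PCT", "CRP", "WBC")),
    trajectory_model
  )
  rules <- unlist(lapply(seq_len(nrow(sched)), function(i) {
    days <- sched$days[[i]]
    pairs <- Map(c, days[-length(days)][-1], days[-1][-1])  # postop pairs
    c(
      list(rule_model(sched$marker[i])),
      lapply(pairs, function(p) rule_model(sched$marker[i], p[1], p[2]))
    )
  }), recursive = FALSE)
  c(raw, traj, rules)
}

#' Evaluate a panel of leak-prediction models
#'
#' Fits/evaluates each requested model on the cohort and returns one ROC
#' summary row per model. Raw-value and trajectory models are scored by the
#' predicted probabilities of a logistic fit (a monotone transform of a
#' single feature, so single-feature AUCs equal the raw-value AUCs); rise
#' rules are binary classifiers summarised by their 2x2 table, with AUC the
#' single-point ROC area (SN + SP)/2. Raw single-day models are scored by
#' the marker value itself (an increasing single-feature logistic score is
#' a monotone transform of it, leaving AUC and the optimal confusion table
#' unchanged), so their cutoffs are reported in marker units.
#'
#' @param cohort A cohort tibble.
#' @param models List of model specs (see [raw_model()]); defaults to
#'   [default_model_panel()].
#' @param window Observation window for trajectory features ("0-5" or
#'   "1-5").
#' @param rules Rise-rule thresholds, as [default_rise_rules()].
#' @param penalty Ridge penalty passed to [fit_logistic()] (default 0).
#' @return A tibble with one [summarise_roc()] row per model, plus a
#'   `type` column.
#' @export
evaluate_marker_panel <- function(cohort, models = default_model_panel(),
                                  window = "0-5",
                                  rules = default_rise_rules(),
                                  penalty = 0) {
  outcomes <- patient_outcomes(cohort)
  labels <- outcomes$al_label
  features <- trajectory_features(cohort, window = window, rules = rules)
  deltas <- delta_table(cohort, window = window, rules = rules)

  rows <- lapply(models, function(m) {
    if (m$type == "raw") {
      sub <- cohort[cohort$marker == m$marker & cohort$day == m$day, ]
      sub <- sub[order(sub$patient_id), ]
      if (nrow(sub) != nrow(outcomes)) {
        abort_data(sprintf("no scheduled %s measurement on day %d",
                           m$marker, m$day))
      }
      # single feature: the logistic score is a monotone transform of the
      # raw value, so scoring by the value itself gives the same AUC and
      # confusion table while keeping the cutoff in marker units
      summarise_roc(sub$value, labels, name = m$name)
    } else if (m$type == "trajectory") {
      x <- slope_matrix(features, m$markers)
      fit <- fit_logistic(x, labels, penalty = penalty)
      scores <- predicted_scores(fit, x)
      out <- summarise_roc(scores, labels, name = m$name)
      out$log_lik <- fit$log_lik
      out
    } else if (m$type == "rule") {
      d <- deltas[deltas$marker == m$marker, ]
      if (!is.null(m$from_day)) {
        d <- d[d$from_day == m$from_day & d$to_day == m$to_day, ]
        if (nrow(d) == 0) {
          abort_data(sprintf("no %s pair POD%d->POD%d", m$marker,
                             m$from_day, m$to_day))
        }
        flag <- tapply(d$rule_flag, d$patient_id, any)
      } else {
        flag <- tapply(d$rule_flag, d$patient_id, any)
      }
      flag <- as.integer(flag[order(names(flag))])
      summarise_roc(flag, labels, name = m$name, binary = TRUE)
    } else {
      abort_config(paste("unknown model type:", m$type))
    }
  })
  res <- dplyr::bind_rows(rows)
  res$type <- vapply(models, function(m) m$type, character(1))
  dplyr::relocate(res, "type", .after = "model")
}
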