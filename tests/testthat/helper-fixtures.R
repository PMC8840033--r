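# Fixture builders shared across test files.

# a tiny deterministic cohort: 4 patients (2 AL), full schedules,
# hand-pickable values via a generator function of (patient index, marker, day)
tiny_cohort <- function(value_fn = function(i, marker, day) i + day) {
  sched <- tidyr::unnest(marker_schedule()[, c("marker", "days")], "days")
  rows <- list()
  for (i in 1:4) {
    for (k in seq_len(nrow(sched))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        patient_id = sprintf("P%04d", i),
        al_label = as.integer(i <= 2),
        marker = sched$marker[k],
        day = sched$days[k],
        value = value_fn(i, sched$marker[k], sched$days[k])
      )
    }
  }
  dplyr::bind_rows(rows)
}

# random score/label fixture with ties (scores drawn from a small integer
# support), guaranteed to contain both classes
random_roc_fixture <- function(n = sample(4:30, 1)) {
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  scores <- sample(1:8, n, replace = TRUE) + sample(c(0, 0.5), n, replace = TRUE)
  list(scores = scores, labels = labels)
}

# brute-force concordance AUC: enumerate all (case, control) pairs
brute_force_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  wins <- 0
  for (a in x) for (b in y) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(x) * length(y))
}

# brute-force Youden scan: best J over every threshold of the form
# "predict positive when score >= t", t ranging over all achievable rules
brute_force_best_j <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  thresholds <- c(sort(unique(scores)), max(scores) + 1)
  best <- -Inf
  for (t in thresholds) {
    pred <- scores >= t
    j <- sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
    best <- max(best, j)
  }
  best
}

# flat-profile config exercising the SD = a * mean^x power law
power_law_config <- function(n = 2000, a = 1, x = 0.8, seed = 7) {
  power_law_sim_config(n_patients = n, a = a, x = x, seed = seed)
}
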