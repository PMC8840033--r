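# Synthetic cohort simulation.
#
# The study data behind the published group summaries are not deposited, so
# analyses here run on synthetic cohorts whose marginal group-wise
# distributions (mean, SD per marker and day) match the published values.

#' Marker measurement schedules
#'
#' CRP and PCT are drawn preoperatively (day 0) and daily through
#' postoperative day (POD) 5; the white-cell count is drawn on days 0, 1, 3
#' and 5 only.
#'
#' @return A tibble with columns `marker`, `unit` and a list-column `days`.
#' @export
marker_schedule <- function() {
  tibble::tibble(
    marker = c("CRP", "PCT", "WBC"),
    unit   = c("mg/L", "ng/mL", "x1000/mm3"),
    days   = list(0:5, 0:5, c(0L, 1L, 3L, 5L))
  )
}

#' Build a cohort simulation configuration
#'
#' @param n_patients Number of patients to simulate.
#' @param prevalence Probability that a patient develops an anastomotic leak
#'   (AL). With `fixed_counts = TRUE` the number of AL patients is fixed at
#'   `round(n_patients * prevalence)` instead of being Bernoulli-drawn.
#' @param group_params Tibble with columns `marker`, `day`, `group`
#'   (`"AL"` or `"noAL"`), `mean`, `sd`; one row per scheduled
#'   (marker, day, group) cell, in marker units.
#' @param rho Within-patient dependence in `[0, 1)`: the correlation between
#'   any two standardized measurements of the same patient, induced by a
#'   shared per-patient standard-normal factor mixed into every draw with
#'   weight `sqrt(rho)`.
#' @param family `"gaussian"` (default) or `"lognormal"`. The lognormal
#'   option is moment-matched: each cell keeps the configured mean and SD
#'   but is right-skewed, which is more faithful to inflammatory markers.
#' @param floor_at_zero Replace negative draws by 0 (concentrations cannot be
#'   negative). Disable to study estimator behaviour on untruncated
#'   Gaussians.
#' @param fixed_counts Use a fixed AL group size instead of Bernoulli
#'   assignment.
#' @param heteroscedastic_power Optional list `list(a =, x =)`. When set, the
#'   per-day noise SD is replaced by `a * m^x` where `m` is the patient's
#'   day mean, so the per-patient (mean, SD) cloud follows the power law
#'   `SD = a * mean^x` used by the variability module.
#' @param level_spread SD (log scale) of a per-patient lognormal level
#'   multiplier applied to all of a patient's day means. Default 0 (all
#'   patients share the group profile); set > 0 to spread patient levels,
#'   e.g. when exercising the power-law fit.
#' @param seed Integer RNG seed stored with the config; `simulate_cohort()`
#'   uses it unless overridden.
#' @return A list of class `sim_config`.
#' @seealso [published_study_config()] for the published parameter set.
#' @export
simulation_config <- function(n_patients,
                              prevalence,
                              group_params,
                              rho = 0.3,
                              family = c("gaussian", "lognormal"),
                              floor_at_zero = TRUE,
                              fixed_counts = FALSE,
                              heteroscedastic_power = NULL,
                              level_spread = 0,
                              seed = NULL) {
  family <- match.arg(family)
  if (n_patients < 1) abort_config("n_patients must be a positive integer")
  if (prevalence < 0 || prevalence > 1) {
    abort_config("prevalence must lie in [0, 1]")
  }
  if (rho < 0 || rho >= 1) abort_config("rho must lie in [0, 1)")
  required <- c("marker", "day", "group", "mean", "sd")
  if (!all(required %in% names(group_params))) {
    abort_config(paste(
      "group_params needs columns:", paste(required, collapse = ", ")
    ))
  }
  if (any(group_params$sd < 0)) abort_config("all sd must be >= 0")
  if (!is.null(heteroscedastic_power)) {
    if (!all(c("a", "x") %in% names(heteroscedastic_power))) {
      abort_config("heteroscedastic_power must be list(a =, x =)")
    }
    if (heteroscedastic_power$a < 0) {
      abort_config("heteroscedastic_power$a must be >= 0")
    }
  }

  # every scheduled (marker, day) needs parameters for both groups
  sched <- tidyr::unnest(marker_schedule(), "days")
  for (g in c("AL", "noAL")) {
    have <- group_params[group_params$group == g, c("marker", "day")]
    miss <- dplyr::anti_join(
      sched, have, by = c("marker", "days" = "day")
    )
    if (nrow(miss) > 0) {
      abort_config(sprintf(
        "missing %s parameters for: %s",
        g, paste(miss$marker, miss$days, sep = "/", collapse = ", ")
      ))
    }
  }

  structure(
    list(
      n_patients = as.integer(n_patients),
      prevalence = prevalence,
      group_params = tibble::as_tibble(group_params),
      rho = rho,
      family = family,
      floor_at_zero = floor_at_zero,
      fixed_counts = fixed_counts,
      heteroscedastic_power = heteroscedastic_power,
      level_spread = level_spread,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Published study parameters as a simulation configuration
#'
#' Returns a configuration pre-filled with the published group-wise mean (SD)
#' of CRP (mg/L), PCT (ng/mL) and WBC (x1000/mm3) at each scheduled day for
#' patients with and without anastomotic leak, an AL prevalence of 22/205,
#' and the study size of 205 patients.
#'
#' @param ... Overrides passed on to [simulation_config()] (e.g.
#'   `n_patients`, `rho`, `fixed_counts`).
#' @return A `sim_config` object.
#' @export
published_study_config <- function(...) {
  grid <- function(marker, group, days, means, sds) {
    tibble::tibble(
      marker = marker, day = days, group = group, mean = means, sd = sds
    )
  }
  gp <- dplyr::bind_rows(
    grid("CRP", "noAL", 0:5,
         c(3.80, 19.80, 44.96, 56.40, 61.02, 58.61),
         c(1.80, 8.25, 28.45, 45.02, 56.90, 65.57)),
    grid("CRP", "AL", 0:5,
         c(3.69, 19.91, 66.03, 111.13, 142.14, 150.90),
         c(2.09, 8.16, 24.77, 51.00, 81.60, 120.17)),
    grid("PCT", "noAL", 0:5,
         c(0.57, 0.84, 1.32, 1.68, 1.99, 2.21),
         c(0.34, 0.45, 0.58, 0.92, 0.95, 1.08)),
    grid("PCT", "AL", 0:5,
         c(0.61, 1.28, 2.22, 3.39, 4.75, 6.31),
         c(0.30, 0.55, 1.15, 1.49, 2.21, 2.65)),
    grid("WBC", "noAL", c(0L, 1L, 3L, 5L),
         c(6.41, 6.96, 7.99, 8.34),
         c(1.60, 1.44, 1.57, 3.34)),
    grid("WBC", "AL", c(0L, 1L, 3L, 5L),
         c(5.85, 6.98, 8.79, 10.01),
         c(0.88, 0.84, 1.13, 1.51))
  )
  defaults <- list(
    n_patients = 205L,
    prevalence = 22 / 205,
    group_params = gp
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Flat-profile configuration for power-law variability studies
#'
#' A single-group configuration in which every marker is flat over its
#' schedule at a common absolute level (default 7000, a white-cell count in
#' cells/mm3), patient levels are spread by a lognormal multiplier, and the
#' measurement noise follows `SD = a * mean^x`. Used to exercise the
#' variability module's power-law fit: the per-patient (mean, SD) cloud
#' then satisfies the power law up to sampling noise. The base level is
#' deliberately large relative to the noise so that error in the
#' within-patient mean does not attenuate the fitted exponent
#' (classical errors-in-variables bias).
#'
#' @param n_patients Number of patients.
#' @param a,x Power-law scale and exponent of the noise SD.
#' @param base_mean Common day mean for every marker and day.
#' @param level_spread Lognormal SD of the per-patient level multiplier.
#' @param seed RNG seed stored with the config.
#' @return A `sim_config` object.
#' @export
power_law_sim_config <- function(n_patients = 2000, a = 1, x = 0.8,
                                 base_mean = 7000, level_spread = 0.5,
                                 seed = NULL) {
  sched <- tidyr::unnest(marker_schedule()[, c("marker", "days")], "days")
  gp <- dplyr::bind_rows(
    tibble::tibble(marker = sched$marker, day = sched$days, group = "noAL",
                   mean = base_mean, sd = 1),
    tibble::tibble(marker = sched$marker, day = sched$days, group = "AL",
                   mean = base_mean, sd = 1)
  )
  simulation_config(
    n_patients = n_patients, prevalence = 0, group_params = gp, rho = 0,
    floor_at_zero = FALSE, heteroscedastic_power = list(a = a, x = x),
    level_spread = level_spread, seed = seed
  )
}

#' Simulate a longitudinal biomarker cohort
#'
#' Draws one cohort from a [simulation_config()]: AL labels
#' (Bernoulli or fixed counts), then per-patient marker values at each
#' scheduled day from the labelled group's (mean, sd), with day-to-day
#' dependence induced by a per-patient shared standard-normal factor.
#' Identical configurations and seeds reproduce identical tables.
#'
#' @param config A `sim_config` object.
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A tibble (the cohort table) with columns `patient_id`,
#'   `al_label` (0/1), `marker`, `day`, `value`; one row per scheduled
#'   measurement.
#' @export
simulate_cohort <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort_config("config must be created by simulation_config()")
  }
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)

  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  if (config$fixed_counts) {
    n_al <- round(n * config$prevalence)
    al <- sample(rep(c(1L, 0L), c(n_al, n - n_al)))
  } else {
    al <- as.integer(stats::runif(n) < config$prevalence)
  }

  z_shared <- stats::rnorm(n)          # per-patient factor, all markers/days
  lvl <- if (config$level_spread > 0) {
    exp(config$level_spread * stats::rnorm(n))
  } else {
    rep(1, n)
  }

  cells <- tidyr::unnest(marker_schedule()[, c("marker", "days")], "days")
  names(cells)[names(cells) == "days"] <- "day"

  grid <- tidyr::crossing(
    tibble::tibble(patient_id = ids, al_label = al,
                   z_shared = z_shared, lvl = lvl),
    cells
  )
  grid$group <- ifelse(grid$al_label == 1L, "AL", "noAL")
  grid <- dplyr::inner_join(
    grid, config$group_params, by = c("marker", "day", "group")
  )
  grid <- dplyr::arrange(grid, .data$patient_id, .data$marker, .data$day)

  mu <- grid$mean * grid$lvl
  sd <- if (is.null(config$heteroscedastic_power)) {
    grid$sd * grid$lvl
  } else {
    config$heteroscedastic_power$a * mu^config$heteroscedastic_power$x
  }

  rho <- config$rho
  z <- sqrt(rho) * grid$z_shared +
    sqrt(1 - rho) * stats::rnorm(nrow(grid))

  value <- if (config$family == "gaussian") {
    mu + sd * z
  } else {
    # moment-matched lognormal: same cell mean and SD, right-skewed
    s2 <- log(1 + (sd / mu)^2)
    value <- exp(log(mu) - s2 / 2 + sqrt(s2) * z)
    value[sd == 0] <- mu[sd == 0]
    value
  }
  if (config$floor_at_zero) value <- pmax(value, 0)

  tibble::tibble(
    patient_id = grid$patient_id,
    al_label = grid$al_label,
    marker = grid$marker,
    day = grid$day,
    value = value
  )
}

#' Read / write a cohort table
#'
#' Cohort tables are exchanged as UTF-8 CSV in long format with a header
#' row and columns `patient_id`, `al_label`, `marker`, `day`, `value`.
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `cohort` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  ch <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      al_label = readr::col_integer(),
      marker = readr::col_character(),
      day = readr::col_integer(),
      value = readr::col_double()
    )
  )
  validate_cohort(ch)
  ch
}

# checks structural invariants of a cohort table
validate_cohort <- function(cohort) {
  needed <- c("patient_id", "al_label", "marker", "day", "value")
  if (!all(needed %in% names(cohort))) {
    abort_data(paste("cohort needs columns:", paste(needed, collapse = ", ")))
  }
  lab <- tapply(cohort$al_label, cohort$patient_id,
                function(x) length(unique(x)))
  if (any(lab != 1)) abort_data("a patient has more than one al_label")
  dup <- duplicated(cohort[, c("patient_id", "marker", "day")])
  if (any(dup)) abort_data("duplicate (patient, marker, day) measurement")
  invisible(cohort)
}
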