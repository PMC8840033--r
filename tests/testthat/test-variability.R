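# Intra-individual variability: within-subject stats, power-law fit, VIM,
# group comparisons.

test_that("within-subject statistics use the n-1 denominator", {
  s <- within_subject_stats(c(1, 2, 3))
  expect_equal(s$within_mean, 2)
  expect_equal(s$within_sd, 1)
  expect_equal(s$cv, 0.5)

  const <- within_subject_stats(rep(7, 4))
  expect_equal(const$within_sd, 0)
  expect_equal(const$cv, 0)

  # scale equivariance: sd scales, cv does not
  set.seed(301)
  v <- rlnorm(6)
  a <- within_subject_stats(v)
  b <- within_subject_stats(3 * v)
  expect_equal(b$within_sd, 3 * a$within_sd)
  expect_equal(b$cv, a$cv)

  expect_error(within_subject_stats(5), class = "leaktraj_data_error")
})

test_that("power-law fit recovers exact relationships", {
  means <- seq(1, 20, length.out = 15)
  fit <- fit_power_law(means, 2 * means^0.5)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$x, 0.5, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)

  # constant SDs: the exponent collapses to ~0
  flat <- fit_power_law(means, rep(3, 15))
  expect_equal(flat$x, 0, tolerance = 1e-6)
  expect_equal(flat$a, 3, tolerance = 1e-6)

  expect_error(fit_power_law(c(1, 2), c(1, 1)),
               class = "leaktraj_data_error")
  expect_error(fit_power_law(rep(2, 5), 1:5), class = "leaktraj_data_error")
})

test_that("VIM identities hold", {
  expect_equal(vim(2, 4, x = 0.5, cohort_mean = 9), 3)
  # exponent zero: VIM is the within-subject SD
  expect_equal(vim(1.7, 12, x = 0, cohort_mean = 5), 1.7)
  # a patient at the cohort mean keeps VIM = SD for any exponent
  expect_equal(vim(2.2, 8, x = 0.73, cohort_mean = 8), 2.2)
  expect_true(is.na(vim(1, 0, x = 0.5, cohort_mean = 2)))
})

test_that("VIM is constant across patients under an exact power law", {
  means <- seq(2, 30, length.out = 20)
  sds <- 1.4 * means^0.62
  fit <- fit_power_law(means, sds)
  v <- vim(sds, means, fit$x, cohort_mean = mean(means))
  expect_lt(diff(range(v)), 1e-8)
})

test_that("generator power law is recovered and VIM de-means the SD", {
  ch <- simulate_cohort(power_law_config(n = 2000, a = 1, x = 0.8, seed = 7))
  idx <- variability_indices(ch)
  fits <- attr(idx, "power_fits")
  for (mk in c("CRP", "PCT")) {          # six measurements per patient
    expect_lt(abs(fits$x[fits$marker == mk] - 0.8), 0.05)
    d <- idx[idx$marker == mk, ]
    expect_gt(cor(d$within_sd, d$within_mean), 0.5)
    expect_lt(abs(cor(d$vim, d$within_mean)), 0.1)
  }
})

test_that("cohort-wide VIM is equivariant under unit rescaling", {
  ch <- simulate_cohort(published_study_config(n_patients = 120L,
                                              fixed_counts = TRUE,
                                              seed = 307L))
  idx <- variability_indices(ch)
  ch2 <- ch
  ch2$value <- ch2$value * 10            # e.g. mg/dL -> mg/L style rescale
  idx2 <- variability_indices(ch2)
  expect_equal(idx2$within_sd, 10 * idx$within_sd, tolerance = 1e-8)
  expect_equal(idx2$vim, 10 * idx$vim, tolerance = 1e-4)
  expect_equal(idx2$cv, idx$cv, tolerance = 1e-8)
})

test_that("min_points excludes sparse patients", {
  ch <- tiny_cohort()
  # drop one patient's WBC down to 2 measurements
  drop <- ch$patient_id == "P0001" & ch$marker == "WBC" & ch$day %in% c(3, 5)
  idx <- variability_indices(ch[!drop, ], min_points = 3)
  expect_false(any(idx$patient_id == "P0001" & idx$marker == "WBC"))
  expect_true(any(idx$patient_id == "P0002" & idx$marker == "WBC"))
})

test_that("group comparison matches brute-force Mann-Whitney U", {
  identical_groups <- compare_groups(c(1, 2, 3, 1, 2, 3),
                                     c(0, 0, 0, 1, 1, 1))
  expect_equal(identical_groups$diff, 0)
  expect_gt(identical_groups$p_value, 0.95)
  expect_lte(identical_groups$ci_low, 0)
  expect_gte(identical_groups$ci_high, 0)

  set.seed(311)
  for (i in 1:50) {
    n1 <- sample(3:10, 1)
    n0 <- sample(3:10, 1)
    g1 <- sample(1:6, n1, replace = TRUE)   # ties on purpose
    g0 <- sample(1:6, n0, replace = TRUE)
    res <- compare_groups(c(g0, g1), rep(c(0, 1), c(n0, n1)))
    u <- sum(outer(g1, g0, ">")) + 0.5 * sum(outer(g1, g0, "=="))
    expect_equal(res$u_stat, u)
    expect_equal(res$diff, mean(g1) - mean(g0))
    expect_lte(res$ci_low, res$diff)
    expect_gte(res$ci_high, res$diff)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(313)
  vals <- rlnorm(40)
  labs <- rep(0:1, 20)
  p1 <- compare_groups(vals, labs)$p_value
  p2 <- compare_groups(exp(vals), labs)$p_value
  p3 <- compare_groups(rank(vals), labs)$p_value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("leak group shows higher CRP within-subject SD on simulated data", {
  ch <- simulate_cohort(published_study_config(n_patients = 2000L,
                                              fixed_counts = TRUE,
                                              seed = 317L))
  idx <- variability_indices(ch)
  cmp <- variability_comparison(idx)
  crp_sd <- cmp[cmp$marker == "CRP" & cmp$index == "SD", ]
  expect_gt(crp_sd$mean_al, crp_sd$mean_no_al)
  expect_lt(crp_sd$p_value, 0.05)
  expect_equal(nrow(cmp), 9)  # 3 markers x SD/CV/VIM
})
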