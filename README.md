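# leaktraj

Tools for analysing 5-day postoperative trajectories of procalcitonin
(PCT, ng/mL), C-reactive protein (CRP, mg/L) and white-blood-cell count
(WBC, ×1000/mm³) as predictors of **anastomotic leak (AL)** after
colorectal surgery — the biomarker-surveillance question that decides
whether an enhanced-recovery patient can be discharged safely before a
leak would declare itself clinically.

The package is aimed at biostatisticians and surgical-outcomes researchers
who want the full analytic chain as tested, reusable functions:

- **Synthetic cohorts** (`simulate_cohort()`): longitudinal marker values
  drawn per (marker, day, outcome group) from configured means/SDs, with a
  per-patient shared factor controlling within-patient correlation;
  `published_study_config()` pre-fills published group parameters (leak
  prevalence 22/205, n = 205, CRP/PCT on days 0–5, WBC on days 0, 1, 3, 5).
- **Trajectory features** (`trajectory_features()`): per-patient OLS slope
  (units/day), consecutive-day deltas, and strict-threshold rise rules
  (> 50 mg/L CRP, > 0.5 ng/mL PCT, > 1.0 ×1000/mm³ WBC between
  consecutive days).
- **Prediction** (`fit_logistic()`, `evaluate_marker_panel()`): logistic
  models by IRLS on single markers, trajectories and their combinations;
  ROC evaluation with concordance AUC (ties ½), DeLong 95% CI and test
  versus the chance diagonal, Youden-index cutoffs (ties toward
  specificity), SN/SP/PPV/NPV. For a two-group Gaussian marker the AUC
  converges to the binormal closed form
  Φ(Δμ/√(σ₀² + σ₁²)), which the test suite verifies.
- **Intra-individual variability** (`variability_indices()`):
  within-subject SD, CV = SD/mean, and VIM — variability independent of
  the mean, SD/meanˣ · (cohort mean)ˣ with x fitted across patients from
  SD = a·meanˣ by nonlinear least squares — compared between outcome
  groups by Mann–Whitney with a Welch-type CI on the mean difference.
- **Design arithmetic** (`finite_population_sample_size()`): Cochran's
  finite-population formula, n = ⌈Nq / ((N−1)e² + q)⌉ with q = z²p(1−p).
- **Pipeline** (`run_pipeline()`): the whole chain as a pure function of
  (input, config, seed), writing a byte-reproducible bundle of CSV tables
  plus a plain-text report.

## Worked example

```r
library(leaktraj)

cfg <- run_config(
  simulation = published_study_config(fixed_counts = TRUE),  # n = 205, 22 leaks
  seed = 42
)
res <- run_pipeline(cfg)
res$panel[res$panel$type == "trajectory",
          c("model", "auc", "ci_low", "ci_high", "p_value")]
#>                    model   auc ci_low ci_high  p_value
#> 1         CRP trajectory 0.799  0.685   0.913 2.83e-07
#> 2         PCT trajectory 0.954  0.876   1.000 5.73e-30
#> 3         WBC trajectory 0.717  0.636   0.798 1.70e-07
#> 4     PCT+CRP trajectory 0.961  0.895   1.000 2.72e-43
#> 5     PCT+WBC trajectory 0.962  0.898   1.000 1.63e-44
#> 6     CRP+WBC trajectory 0.825  0.732   0.919 9.62e-12
#> 7 PCT+CRP+WBC trajectory 0.967  0.912   1.000 1.17e-61
```

On this simulated 205-patient cohort the PCT trajectory separates leak
from no-leak patients far better than CRP or WBC (AUC 0.95 vs 0.80/0.72),
and combining trajectories adds a little more; every AUC differs from the
0.5 chance diagonal (p_value column). Variability indices tell the same
story per marker:

```r
res$variability[res$variability$marker == "PCT", ]
#>   marker index mean_no_al mean_al   diff  ci_low ci_high u_stat  p_value
#> 1    PCT    SD      0.878   2.678 1.7994  1.4661   2.133   4019 2.34e-14
#> 2    PCT    CV      0.633   0.838 0.2046  0.1263   0.283   3379 2.04e-07
#> 3    PCT   VIM      1.120   1.193 0.0733 -0.0584   0.205   2542 4.42e-02
```

Leak patients have much larger within-subject SD and CV; VIM — the SD with
its mean-dependence removed — shows only a marginal difference, i.e. most
of the extra "variability" in leak patients is their rising mean level.
Deterministic report numbers come straight from the formulas:

```r
finite_population_sample_size(420, margin = 0.05, confidence = 0.95)
#> [1] 201
confusion_metrics(confusion_table(tp = 17, fp = 6, fn = 5, tn = 177))
#> SN 77.3%, SP 96.7%, PPV 73.9%, NPV 97.3% (rounded to 1 d.p.)
```

See the vignette (`vignettes/biomarker-trajectories.Rmd`) for the model,
the design decisions and what synthetic-cohort results do and do not show.

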