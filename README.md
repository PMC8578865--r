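# plastidx

Composite-biomarker analysis for longitudinal antidepressant trials, built
around the **neuroplasticity index (NI)** — the ratio of serum
brain-derived neurotrophic factor (BDNF, pg/ml) to the 24-item Hamilton
Depression Rating Scale (HAMD-24) score:

```
NI = BDNF / HAMD-24        (pg/ml per severity point)
NI enhancement(d1, d2) = NI_d2 − NI_d1
```

Serum BDNF runs low in major depressive disorder but by itself does not
predict who will respond to treatment. The index normalises the
neurotrophic signal by rated severity, and its *early* enhancement (first
post-baseline blood draw minus baseline) is used to predict the four-week
outcome, defined as a HAMD-24 reduction rate `(H0 − H28)/H0 ≥ 60%`
("quasi-effective" response). The package is aimed at biostatisticians
analysing small two-arm antidepressant trials with repeated symptom scales
and sparse blood draws.

What it provides, end to end:

* **Trial I/O** — validated long-format CSV ingestion (subject × visit-day
  rows; missing-value tokens `""`/`NA`/`NaN`), enrollment filtering
  (baseline HAMD-24 ≥ 20, QIDS-SR16 ≥ 5, whole-subject exclusion), and
  per-analysis complete-case subsetting.
* **NI core** — NI tables, all pairwise enhancements, reduction rates, and
  inclusive-threshold responder classification.
* **Longitudinal inference, from first principles** — Pearson correlation
  with exact small-sample t/p; one-way repeated-measures ANOVA with the
  Greenhouse–Geisser ε correction; split-plot drug-by-time ANOVA; paired
  baseline contrasts (raw + Bonferroni); Welch two-sample t.
* **ROC analysis** — empirical staircase, trapezoidal AUC (provably equal
  to the tie-aware pair-counting statistic), Youden-optimal operating
  points, optional seeded bootstrap CIs; `lower_is_positive` orientation
  for markers that run low in cases.
* **A calibrated synthetic-trial generator** — a latent-trait model of two
  study designs (single-arm n=15 + 11 healthy controls; two-arm 18+18 with
  4 missing blood series per arm) with exact closed-form population
  summaries (`expected_structure()`) for oracle-checked parameter
  recovery.
* **Pipeline** — `run_all()` orchestrates every analysis, returns a tidy
  report object and writes CSV tables plus a text summary; all result
  types have `tidy()`/`glance()` and `autoplot()` methods. A thin CLI
  lives in `inst/scripts/ni_pipeline.R` (`simulate` / `analyze`).

## Worked example

```r
library(plastidx)

bundle <- simulate_study(generator_config())   # deterministic default bundle
cfg    <- analysis_config()                    # early day 7 (trial 1) / 4 (trial 2)
report <- run_all(bundle$trial1, bundle$trial2, bundle$controls, cfg)
report
#> Neuroplasticity-index analysis report
#>   pooled baseline BDNF~HAMD: R^2 = 0.145, p = 0.01298 (n = 42)
#>   trial1 diagnosis AUC = 1.000
#>   trial1 prediction AUC (yueju) = 1.000
#>   trial2 prediction AUC (yueju) = 0.911
#>   trial2 prediction (escitalopram): skipped
```

Reading the output: pooled across both trials, baseline serum BDNF and
HAMD-24 are negatively correlated (R² = 0.145, p = 0.013, n = 42
patients); baseline BDNF separates patients from healthy controls
(diagnosis ROC); early NI enhancement predicts ≥60% responders in the
active arm (prediction AUC 0.91–1.00), while the comparison arm has no
responders at four weeks, so its prediction ROC is skipped — exactly the
structural outcome such trials report.

Individual stages are ordinary tibble-in/tibble-out functions:

```r
run_symptom_timecourse(bundle$trial2, "hamd24", "yueju")
#> Time course of hamd24, arm yueju (n = 18; days 0/4/7/14/28)
#> Repeated-measures ANOVA (n = 18 subjects, k = 5 conditions)
#>   time:  F(4, 68) = 192.484, p = 2.658e-36 (uncorrected)
#>   GG:    eps = 0.517, F(2.067, 35.14), p = 7.69e-20

roc <- run_roc_suite(bundle$trial1, bundle$controls, cfg)
roc$diagnosis
#> ROC (lower_is_positive): AUC = 1.0000 (14 positives, 11 negatives)
#>   Youden-optimal threshold 1.995e+04: sensitivity 100.0%, specificity 100.0%
```

The repeated-measures F is reported both uncorrected and with
Greenhouse–Geisser–corrected degrees of freedom (ε = 0.517 here, i.e., a
clear sphericity violation); the diagnosis ROC is oriented so that *low*
BDNF marks a case.

See `vignettes/neuroplasticity-index-methods.Rmd` for the model, the
generator's latent structure and calibration, and all numerical
conventions.

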