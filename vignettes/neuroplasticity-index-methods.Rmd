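---
title: "Methods: the neuroplasticity index and its analysis pipeline"
author: "plastidx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the neuroplasticity index and its analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidx)
```

## The scientific problem

Conventional antidepressants act slowly; a marker available within the first
days of treatment that predicts the four-week outcome would let clinicians
change course early. Serum brain-derived neurotrophic factor (BDNF, pg/ml)
is depressed in major depressive disorder (MDD) but is, on its own, a poor
predictor of treatment response. The composite studied here is the
**neuroplasticity index**

$$\mathrm{NI} = \frac{\text{serum BDNF (pg/ml)}}{\text{HAMD-24 score}},$$

the amount of circulating neurotrophic signal per point of clinician-rated
severity, and its **enhancement** $\Delta\mathrm{NI}(d_1, d_2) =
\mathrm{NI}_{d_2} - \mathrm{NI}_{d_1}$ over a treatment interval. The
package implements the full analysis such a two-trial study needs: validated
ingestion of subject-by-visit tables, enrollment filtering, NI and responder
computation, longitudinal inference, ROC analysis, and a calibrated
synthetic-data generator, because patient-level data of this kind are
typically not deposited.

## Analysis conventions

* **Responder rule.** A subject responds ("quasi-effective" outcome) when
  the HAMD-24 reduction rate $(H_0 - H_{28})/H_0$ reaches 60% by day 28.
  The comparison is *inclusive* (`>=`), configurable via
  `analysis_config(responder_threshold=)`. We read the threshold as a
  minimum, as is standard for response criteria.
* **Early visit.** Trial-dependent: the first post-baseline blood draw (day
  7 in the single-arm trial, day 4 in the two-arm trial), supplied by
  configuration rather than hard-coded.
* **Undefined NI.** A post-treatment HAMD-24 of 0 (full remission) makes
  the ratio undefined. We exclude that visit's NI and log it instead of
  imputing a floor: any floor is arbitrary, and remitted subjects no longer
  need outcome prediction.
* **Missing data.** Enrollment exclusion is whole-subject; analysis
  subsetting is complete-case *per analysis* (each analysis declares its
  own variables and days, so the effective n legitimately differs between,
  say, the symptom time course and the BDNF time course). Nothing is
  imputed. NI is computed only from same-day BDNF/HAMD pairs.
* **Significance.** All p values are two-tailed at $\alpha = 0.05$.

## Inferential machinery

The longitudinal statistics are implemented from their definitions, because
the sums-of-squares decompositions themselves are what the test suite
verifies against brute-force oracles.

* **Pearson correlation** on raw values, with
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, two-tailed.
* **One-way repeated-measures ANOVA**: total SS split into subject, time
  and error strata; $F = MS_{time}/MS_{error}$. Sphericity is corrected by
  the **Greenhouse–Geisser** $\hat\epsilon$ computed from the
  double-centered sample covariance of the conditions,
  $\hat\epsilon = (\mathrm{tr}\,S^*)^2 / \big((k-1)\sum_{ij} s^{*2}_{ij}\big)$,
  clamped to $[1/(k-1), 1]$. Both the uncorrected p (exact under
  sphericity) and the corrected p are reported; Greenhouse–Geisser was
  chosen over Huynh–Feldt as the conservative default. Under true
  sphericity the corrected test is mildly conservative — this is a property
  of the estimator, not a defect, and the type-I-error test accounts for it.
* **Split-plot (drug-by-time) ANOVA** for the randomized trial: group
  tested against subjects-within-group, time and interaction against the
  within error, with $\hat\epsilon$ from the pooled within-group
  covariance.
* **Baseline contrasts**: paired t of each visit against day 0, reported
  raw and Bonferroni-adjusted (default display: raw, since no correction is
  canonical here). Zero-variance differences yield the degenerate
  $t = \pm\infty$, $p = 0$ (or $t = 0$, $p = 1$ for identical columns) and
  are flagged rather than mangled.
* **Welch t** for cross-sectional contrasts (patients vs healthy
  controls); the unequal-variance form is the robust default.
* **ROC**: thresholds at the distinct score values, trapezoidal AUC —
  equal by construction to the pair-counting (Mann–Whitney) statistic with
  half-credit for ties, which doubles as an exact independent oracle.
  Markers where cases run *low* (serum BDNF) use the
  `lower_is_positive` orientation. Operating points maximize Youden's
  $J$; ties break toward higher sensitivity, then toward the threshold
  calling more cases. The selection rule is an assumption (the common
  clinical default); closest-to-(0,1) is available. Bootstrap CIs are
  optional and seeded.

## The synthetic-data generator

`generator_config()` + `simulate_study()` emulate the two study designs:
a single-arm observation (15 patients; scales on days 0/7/14/28; blood on
0/7/28; 11 healthy controls; one failed blood series) and a two-arm
randomized comparison (18 per arm; scales 0/4/7/14/28; blood 0/4/28; four
failed blood series per arm, whole-subject as when a draw fails).

### Generative model

Per patient $i$ the latent layer is linear-Gaussian:

* severity $s_i \sim N(0, \sigma_s^2)$ shifting the whole HAMD-24
  trajectory;
* a stable **neuroplasticity trait** $t_i$ (sd `trait_sd`, in NI units)
  shifting NI at every visit, with
  $\mathrm{cor}(t_i, s_i) = -\texttt{trait\_coupling}$ — severe patients
  tend to carry less neurotrophic reserve, which produces the negative
  baseline BDNF–HAMD correlation;
* a **response gain** $g_i \sim N(1, \texttt{response\_sd}^2)$, per arm.

Enrollment truncates at the floor: the baseline triple
$(s_i, t_i, \varepsilon_{H,0})$ is resampled until the observed baseline
HAMD-24 is at least 20, keeping the distribution smooth instead of clipped.

HAMD-24 improves multiplicatively,
$H_{i,d} = (h_0 + s_i)\,e^{\delta_d g_i} + \varepsilon$, with $\delta_d$
solved so the arm's *mean* change per day equals the configured
`hamd_change`. The multiplicative form keeps scores positive under
response heterogeneity and yields a realistic right-skewed reduction-rate
distribution; scores are rounded and floored at 0 (BDNF at 1 pg/ml).

NI is the directly parameterized layer:
$$\mathrm{NI}_{i,d} = \beta_d (m_0 + t_i) + \gamma_d (g_i - 1) +
\varepsilon_{N},$$
with $\beta_0 = 1,\ \gamma_0 = 0$. The per-day scale $\beta_d$ is solved in
closed form so the implied mean serum BDNF matches the configured
`bdnf_change` exactly (including the enrollment-truncation and
response-gain cross terms), and BDNF is emitted as
$B_{i,d} = \mathrm{NI}_{i,d} \times H_{i,d}$. Generating the index rather
than the ratio of two noisy Gaussians is what makes the population NI
autocorrelations exactly closed-form. The gain loading is
$\gamma_d = \psi\,(m_d - m_0)$ up to the early blood draw
($\psi$ = `response_ni_gain`) and then saturates at its early value: the
gain governs how fast a subject's index rises, while the late index is
dominated by the trait-proportional amplification. This is also what makes
*early* NI enhancement (essentially $\gamma_{early}(g_i-1)$ plus noise)
predictive of final response (a threshold on $g_i$), while baseline NI
alone is not.

`expected_structure()` returns the closed-form population values the model
implies — mean baseline BDNF per group, the baseline BDNF–HAMD
correlation (via the first four moments of the truncated enrollment
variable), and the NI correlation for every blood-day pair — and the test
suite checks them against an independently coded Monte-Carlo simulation of
the continuous model ($n = 10^5$, agreement within three Monte-Carlo
standard errors) and against the full pipeline at $n = 500$ per arm. The
only departures of the emitted data from the continuous core are integer
rounding of scale scores and the rare physical floors.

### Default calibration

Absolute BDNF levels are assay-dependent, and the source designs publish
no distributional parameters, so the defaults are placeholders chosen once
to reproduce the qualitative structure such data show, not any particular
dataset: controls at 24000 ± 3500 pg/ml with an 8000 pg/ml patient deficit
(baseline separation AUC ≈ 0.95); baseline HAMD-24 26 ± 4 truncated at 20;
`trait_sd` 180 and coupling 0.9 (baseline BDNF–HAMD correlation ≈ −0.39,
NI autocorrelations in the 0.6–0.9 band); active-arm HAMD falling ~70% by
day 28 with BDNF recovering most of the deficit, comparison arm falling
~30% with BDNF exactly flat. The comparison arm's mean reduction sits well
below the 60% responder threshold with low response heterogeneity
(`response_sd` 0.2 vs 0.3), so that arm reproducibly lacks responders and
exercises the "prediction ROC skipped" path — the structural situation the
analysis must handle. This deliberately sacrifices equality of the two
arms' mean symptom improvement; the generator emphasizes the
responder-imbalance structure over matched efficacy.

### What the generator does *not* emulate

No pharmacokinetics, no visit-level dropout of scale assessments, no
item-level instrument structure, no placebo response dynamics, and the
self-rated scales (QIDS-SR16, PHQ-9) are simple linear maps of the same
latent improvement. Passing tests therefore demonstrate the correctness of
the *analysis machinery* under a plausible data-generating process, not
clinical properties of real populations.

## Worked example

```{r example}
bundle <- simulate_study(generator_config())
cfg <- analysis_config()
report <- run_all(bundle$trial1, bundle$trial2, bundle$controls, cfg)
report
```

```{r suite}
run_ni_correlation_suite(bundle$trial2, "yueju", cfg)[, c("pairing", "n", "r_squared", "p_value")]
```

## Numerical and design notes

* Degenerate inputs: constant vectors are a correlation error; zero error
  variance gives $F \in \{0, \infty\}$ by the documented convention;
  single-class labels are an ROC error (and a logged skip in the
  pipeline); `gg_epsilon` returns 1 when the double-centered covariance
  vanishes.
* Problem sizes: the test suite uses 200-instance oracle sweeps, 1000-run
  type-I simulations at 10 subjects × 4 visits, and parameter recovery at
  500 subjects per arm — sizes at which every Monte-Carlo band quoted
  above is meaningful while the whole suite runs in well under a minute.
* Printed F statistics in small clinical reports are often irreconcilable
  with the stated design sizes (degrees of freedom mixing corrected and
  uncorrected conventions); this package always reports the textbook df
  and both p values, and makes no attempt to mimic any one software
  package's reporting.
* Reproducibility: every simulation is a pure function of its config and
  seed; `run_all()` rerun on the same inputs writes byte-identical tables.
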