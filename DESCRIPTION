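Package: plastidx
Title: Neuroplasticity-Index Biomarker Analysis for Antidepressant Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for composite-biomarker analysis of longitudinal
    antidepressant trials built around the neuroplasticity index (NI), the
    ratio of serum brain-derived neurotrophic factor (BDNF, pg/ml) to the
    24-item Hamilton Depression Rating Scale (HAMD-24) score. Provides
    validated ingestion of long-format subject-by-visit tables, enrollment
    filtering and per-analysis complete-case subsetting, NI and NI-enhancement
    computation, responder classification by HAMD-24 reduction rate,
    from-first-principles longitudinal inference (Pearson correlation,
    one-way repeated-measures ANOVA with Greenhouse-Geisser correction,
    split-plot drug-by-time ANOVA, baseline contrasts, Welch t), empirical
    ROC/AUC analysis with Youden-optimal operating points, a seeded
    latent-trait simulator of two-arm trial data with closed-form population
    summaries, and a pipeline orchestrating the full analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
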