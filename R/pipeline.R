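#' Analysis configuration
#'
#' Binds the analysis-level choices: which visit counts as the "early"
#' treatment time in each trial (day 7 in the single-arm trial, day 4 in the
#' two-arm trial, following each schedule's first post-baseline blood draw),
#' the final visit, the responder threshold on the HAMD-24 reduction rate,
#' the post-hoc multiplicity correction, and the two-tailed significance
#' level.
#'
#' @param early_day Named list of early visit days per trial.
#' @param final_day Final visit day (default 28).
#' @param responder_threshold Fraction in (0, 1]; default 0.60 (inclusive).
#' @param posthoc_correction `"none"` (default; results also carry
#'   Bonferroni-adjusted p values) or `"bonferroni"`.
#' @param alpha Two-tailed significance level (default 0.05).
#' @param seed Seed for any bootstrap resampling.
#' @return A list with class `"analysis_config"`.
#' @export
analysis_config <- function(early_day = list(trial1 = 7L, trial2 = 4L),
                            final_day = 28L,
                            responder_threshold = 0.60,
                            posthoc_correction = c("none", "bonferroni"),
                            alpha = 0.05,
                            seed = 1L) {
  posthoc_correction <- match.arg(posthoc_correction)
  stopifnot(responder_threshold > 0, responder_threshold <= 1,
            all(unlist(early_day) < final_day))
  structure(list(early_day = early_day, final_day = final_day,
                 responder_threshold = responder_threshold,
                 posthoc_correction = posthoc_correction,
                 alpha = alpha, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Symptom (or BDNF) time-course analysis for one arm
#'
#' Complete-cases the requested measure over its scheduled days within one
#' arm, runs the one-way repeated-measures ANOVA with Greenhouse--Geisser
#' correction, and the paired baseline contrasts.
#'
#' @param data A validated trial tibble (one trial).
#' @param measure One of `"hamd24"`, `"qids_sr16"`, `"phq9"`, `"bdnf"`.
#' @param arm Arm to analyse.
#' @param days Visit days to use; default: all days at which the measure is
#'   observed for at least one subject of the arm.
#' @param correction Post-hoc correction passed to [posthoc_vs_baseline()].
#' @return A list with class `"timecourse_result"`: `anova` (an
#'   [rm_anova_oneway()] result), `posthoc` (baseline contrasts with both
#'   raw and adjusted p), `n`, `days`, `measure`, `arm`.
#' @export
run_symptom_timecourse <- function(data, measure = "hamd24", arm = "yueju",
                                   days = NULL,
                                   correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(measure %in% MEASURE_VARS)
  sub <- data[data$arm == arm, , drop = FALSE]
  if (nrow(sub) == 0) rlang::abort(paste0("no records for arm '", arm, "'"))
  if (is.null(days)) {
    days <- sort(unique(sub$day[!is.na(sub[[measure]])]))
  }
  if (length(days) < 2) rlang::abort("need at least 2 usable days")
  m <- pivot_measure_matrix(sub, measure, days)
  if (nrow(m) < 2) rlang::abort("need at least 2 complete-case subjects")
  res <- rm_anova_oneway(m)
  ph <- posthoc_vs_baseline(m, baseline_index = 1L, correction = "bonferroni")
  ph_raw <- posthoc_vs_baseline(m, baseline_index = 1L, correction = "none")
  ph$p_bonferroni <- ph$p_adjusted
  ph$p_adjusted <- if (correction == "none") ph_raw$p_adjusted else ph$p_bonferroni
  structure(list(anova = res, posthoc = ph, n = nrow(m),
                 days = days, measure = measure, arm = arm),
            class = "timecourse_result")
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf("Time course of %s, arm %s (n = %d; days %s)\n",
              x$measure, x$arm, x$n, paste(x$days, collapse = "/")))
  print(x$anova)
  invisible(x)
}

#' NI correlation suite for one arm
#'
#' Computes the canonical NI pairings for an arm: the NI--NI correlations
#' (baseline vs early, baseline vs final, early vs final) and the
#' NI--enhancement correlations (early NI vs early enhancement, final NI vs
#' final enhancement, early NI vs final enhancement), each on that pairing's
#' complete cases. Pairings with fewer than 3 usable subjects are skipped
#' with a logged reason.
#'
#' @param data A validated trial tibble (one trial).
#' @param arm Arm to analyse.
#' @param config An [analysis_config()].
#' @return A tibble `arm, pairing, var_x, var_y, n, r, r_squared, t_stat,
#'   df, p_value`; skipped pairings appear with `n` and `NA` statistics and
#'   the reason in `note`.
#' @export
run_ni_correlation_suite <- function(data, arm, config = analysis_config()) {
  trial <- unique(data$trial[data$arm == arm])
  if (length(trial) != 1) rlang::abort("arm must belong to exactly one trial")
  early <- config$early_day[[trial]]
  final <- config$final_day
  nit <- ni_table(data[data$arm == arm, , drop = FALSE])
  wide <- tidyr::pivot_wider(nit[, c("subject_id", "day", "ni")],
                             names_from = "day", values_from = "ni",
                             names_prefix = "d")
  gv <- function(d) {
    col <- paste0("d", d)
    if (col %in% names(wide)) wide[[col]] else rep(NA_real_, nrow(wide))
  }
  ni0 <- gv(0); ni_e <- gv(early); ni_f <- gv(final)
  specs <- list(
    list(pairing = "ni_baseline_vs_early", x = ni0, y = ni_e,
         vx = "ni_d0", vy = paste0("ni_d", early)),
    list(pairing = "ni_baseline_vs_final", x = ni0, y = ni_f,
         vx = "ni_d0", vy = paste0("ni_d", final)),
    list(pairing = "ni_early_vs_final", x = ni_e, y = ni_f,
         vx = paste0("ni_d", early), vy = paste0("ni_d", final)),
    list(pairing = "early_ni_vs_early_enhancement", x = ni_e, y = ni_e - ni0,
         vx = paste0("ni_d", early), vy = paste0("enh_d0_d", early)),
    list(pairing = "final_ni_vs_final_enhancement", x = ni_f, y = ni_f - ni0,
         vx = paste0("ni_d", final), vy = paste0("enh_d0_d", final)),
    list(pairing = "early_ni_vs_final_enhancement", x = ni_e, y = ni_f - ni0,
         vx = paste0("ni_d", early), vy = paste0("enh_d0_d", final))
  )
  rows <- lapply(specs, function(sp) {
    ok <- !is.na(sp$x) & !is.na(sp$y)
    n <- sum(ok)
    base <- tibble(arm = arm, pairing = sp$pairing, var_x = sp$vx,
                   var_y = sp$vy, n = n)
    if (n < 3) {
      inform(paste0("skipping ", sp$pairing, " for arm ", arm,
                    ": only ", n, " complete pairs"))
      return(dplyr::mutate(base, r = NA_real_, r_squared = NA_real_,
                           t_stat = NA_real_, df = NA_integer_,
                           p_value = NA_real_, note = "insufficient n"))
    }
    ct <- pearson_test(sp$x[ok], sp$y[ok])
    dplyr::mutate(base, r = ct$r, r_squared = ct$r_squared, t_stat = ct$t_stat,
                  df = ct$df, p_value = ct$p_value, note = "")
  })
  dplyr::bind_rows(rows)
}

#' ROC suite: diagnosis and prediction
#'
#' Two receiver-operating-characteristic analyses:
#' * **Diagnosis** — baseline serum BDNF separating patients (positive
#'   class, lower values) from healthy controls; orientation
#'   `lower_is_positive`.
#' * **Prediction** — per arm, the early NI enhancement (early day minus
#'   baseline) predicting final responder status at the configured
#'   reduction-rate threshold; orientation `higher_is_positive`. If an
#'   arm's responder labels are single-class (e.g. no subject reaches the
#'   threshold) that arm's ROC is skipped with a logged reason.
#'
#' @param data A validated trial tibble (one trial).
#' @param controls A control tibble (`subject_id, arm, bdnf`), or `NULL` to
#'   skip the diagnosis ROC.
#' @param config An [analysis_config()].
#' @return A list with class `"roc_suite"`: `diagnosis` (a
#'   [roc_curve()] result or `NULL`), `prediction` (named list per arm:
#'   either a `roc_result` or a skip record `list(skipped, reason,
#'   n_responder, n_nonresponder)`), `threshold`.
#' @export
run_roc_suite <- function(data, controls, config = analysis_config()) {
  trial <- unique(data$trial)
  if (length(trial) != 1) rlang::abort("data must hold exactly one trial")
  early <- config$early_day[[trial]]
  diagnosis <- NULL
  if (!is.null(controls) && nrow(controls) > 0) {
    base_bdnf <- data[data$day == 0 & !is.na(data$bdnf), ]
    scores <- c(base_bdnf$bdnf, controls$bdnf)
    labels <- c(rep(TRUE, nrow(base_bdnf)), rep(FALSE, nrow(controls)))
    diagnosis <- roc_curve(scores, labels, orientation = "lower_is_positive")
  } else {
    inform("no controls supplied: diagnosis ROC skipped")
  }
  resp <- classify_responders(data, baseline_day = 0L,
                              final_day = config$final_day,
                              threshold = config$responder_threshold)
  enh <- ni_enhancement_table(data)
  enh <- enh[enh$day_from == 0 & enh$day_to == early, ]
  prediction <- list()
  for (arm in unique(data$arm)) {
    lab <- dplyr::inner_join(resp[resp$arm == arm, c("subject_id", "responder")],
                             enh[enh$arm == arm, c("subject_id", "enhancement")],
                             by = "subject_id")
    n_r <- sum(lab$responder); n_n <- sum(!lab$responder)
    if (nrow(lab) < 2 || n_r == 0 || n_n == 0) {
      inform(paste0("prediction ROC skipped for arm ", arm, ": ", n_r,
                    " responders / ", n_n, " non-responders among ",
                    nrow(lab), " evaluable subjects"))
      prediction[[arm]] <- list(skipped = TRUE,
                                reason = "insufficient responders or non-responders",
                                n_responder = n_r, n_nonresponder = n_n)
    } else {
      prediction[[arm]] <- roc_curve(lab$enhancement, lab$responder,
                                     orientation = "higher_is_positive")
    }
  }
  structure(list(diagnosis = diagnosis, prediction = prediction,
                 threshold = config$responder_threshold, early_day = early),
            class = "roc_suite")
}

#' Run the complete two-trial analysis
#'
#' Orchestrates every stage on both trials: symptom time courses per scale
#' and arm, BDNF time courses (with the healthy-control contrast in trial
#' 1), the pooled-baseline BDNF--HAMD correlation across trials, the NI
#' correlation suite per arm, responder classification, the drug-by-time
#' split-plot ANOVA in trial 2, and the two ROC analyses. A failing stage is
#' recorded with its error message; the remaining stages still run.
#'
#' @param trial1,trial2 Validated trial tibbles, or paths to their CSVs.
#' @param controls Control tibble or CSV path, or `NULL`.
#' @param config An [analysis_config()].
#' @param output_dir Optional directory; when given, tidy CSV tables and a
#'   human-readable summary are written there.
#' @return A list with class `"ni_report"`; see the methods vignette for
#'   the section-by-section contents. `errors` lists any failed stages.
#' @export
run_all <- function(trial1, trial2, controls = NULL,
                    config = analysis_config(), output_dir = NULL) {
  as_trial <- function(x, expected) {
    if (is.character(x)) read_trial_table(x, expected) else x
  }
  t1 <- as_trial(trial1, "trial1")
  t2 <- as_trial(trial2, "trial2")
  ctl <- if (is.character(controls)) read_control_table(controls) else controls
  errors <- list()
  try_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      inform(paste0("stage '", name, "' failed: ", conditionMessage(e)))
      NULL
    })
  }
  symptom <- list()
  for (tr in c("trial1", "trial2")) {
    dat <- if (tr == "trial1") t1 else t2
    for (arm in intersect(unique(dat$arm), PATIENT_ARMS)) {
      for (sc in c("hamd24", "qids_sr16", "phq9")) {
        key <- paste(tr, arm, sc, sep = ".")
        symptom[[key]] <- try_stage(key, run_symptom_timecourse(
          dat, sc, arm, correction = config$posthoc_correction))
      }
    }
  }
  bdnf_tc <- list()
  for (tr in c("trial1", "trial2")) {
    dat <- if (tr == "trial1") t1 else t2
    for (arm in intersect(unique(dat$arm), PATIENT_ARMS)) {
      key <- paste(tr, arm, "bdnf", sep = ".")
      bdnf_tc[[key]] <- try_stage(key, run_symptom_timecourse(
        dat, "bdnf", arm, correction = config$posthoc_correction))
    }
  }
  control_contrast <- NULL
  if (!is.null(ctl)) {
    control_contrast <- try_stage("control_contrast", {
      base <- t1[t1$day == 0 & !is.na(t1$bdnf), ]
      welch_t_test(base$bdnf, ctl$bdnf)
    })
  }
  pooled_baseline <- try_stage("pooled_baseline_correlation", {
    base <- dplyr::bind_rows(t1, t2)
    base <- base[base$day == 0 & !is.na(base$bdnf) & !is.na(base$hamd24), ]
    pearson_test(base$bdnf, base$hamd24)
  })
  pooled_final <- try_stage("pooled_final_correlation", {
    fin <- dplyr::bind_rows(t1, t2)
    fin <- fin[fin$day == config$final_day & !is.na(fin$bdnf) & !is.na(fin$hamd24), ]
    pearson_test(fin$bdnf, fin$hamd24)
  })
  ni_cors <- list()
  for (tr in c("trial1", "trial2")) {
    dat <- if (tr == "trial1") t1 else t2
    for (arm in intersect(unique(dat$arm), PATIENT_ARMS)) {
      key <- paste(tr, arm, sep = ".")
      ni_cors[[key]] <- try_stage(paste0("ni_correlations.", key),
                                  run_ni_correlation_suite(dat, arm, config))
    }
  }
  responders <- list(
    trial1 = try_stage("responders.trial1", classify_responders(
      t1, 0L, config$final_day, config$responder_threshold)),
    trial2 = try_stage("responders.trial2", classify_responders(
      t2, 0L, config$final_day, config$responder_threshold))
  )
  drug_time <- try_stage("drug_time_anova", {
    days <- sort(unique(t2$day[!is.na(t2$hamd24)]))
    cc <- complete_cases(t2, "hamd24", days)
    m <- pivot_measure_matrix(cc, "hamd24", days)
    grp <- cc$arm[match(rownames(m), cc$subject_id)]
    mixed_anova(m, grp)
  })
  roc <- list(
    trial1 = try_stage("roc.trial1", run_roc_suite(t1, ctl, config)),
    trial2 = try_stage("roc.trial2", run_roc_suite(t2, NULL, config))
  )
  report <- structure(list(
    symptom_timecourse = symptom,
    bdnf_timecourse = bdnf_tc,
    control_contrast = control_contrast,
    pooled_baseline_correlation = pooled_baseline,
    pooled_final_correlation = pooled_final,
    ni_correlations = ni_cors,
    responders = responders,
    drug_time_anova = drug_time,
    roc = roc,
    config = config,
    errors = errors
  ), class = "ni_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

sig_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < 0.001 ~ "***", p < 0.01 ~ "**",
                   p < 0.05 ~ "*", TRUE ~ "")
}

#' Write an analysis report to tidy CSV tables plus a text summary
#'
#' @param report An `"ni_report"` from [run_all()].
#' @param output_dir Directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  tc_rows <- purrr::imap(c(report$symptom_timecourse, report$bdnf_timecourse),
    function(x, key) {
      if (is.null(x)) return(NULL)
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      td <- tidy(x$anova)
      dplyr::mutate(td, trial = parts[1], arm = parts[2], measure = parts[3],
                    n = x$n, .before = 1)
    })
  tc <- dplyr::bind_rows(tc_rows)
  if (nrow(tc) > 0) {
    tc$signif <- sig_stars(tc$p_gg)
    readr::write_csv(tc, file.path(output_dir, "timecourse_anova.csv"), na = "NA")
  }
  ni <- purrr::imap(report$ni_correlations, function(x, key) {
    if (is.null(x)) return(NULL)
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    dplyr::mutate(x, trial = parts[1], .before = 1)
  }) |> dplyr::bind_rows()
  if (nrow(ni) > 0) {
    ni$signif <- sig_stars(ni$p_value)
    readr::write_csv(ni, file.path(output_dir, "ni_correlations.csv"), na = "NA")
  }
  resp <- purrr::imap(report$responders, function(x, tr) {
    if (is.null(x)) return(NULL)
    dplyr::mutate(as_tibble(x), trial = tr, .before = 1)
  }) |> dplyr::bind_rows()
  if (nrow(resp) > 0) {
    readr::write_csv(resp, file.path(output_dir, "responders.csv"), na = "NA")
  }
  roc_rows <- list()
  for (tr in names(report$roc)) {
    suite <- report$roc[[tr]]
    if (is.null(suite)) next
    if (!is.null(suite$diagnosis)) {
      roc_rows[[paste0(tr, ".diagnosis")]] <- dplyr::mutate(
        glance(suite$diagnosis), trial = tr, analysis = "diagnosis",
        arm = "patients_vs_controls", .before = 1)
    }
    for (arm in names(suite$prediction)) {
      pr <- suite$prediction[[arm]]
      if (inherits(pr, "roc_result")) {
        roc_rows[[paste0(tr, ".", arm)]] <- dplyr::mutate(
          glance(pr), trial = tr, analysis = "prediction", arm = arm, .before = 1)
        readr::write_csv(pr$points,
                         file.path(output_dir, paste0("roc_points_", tr, "_", arm, ".csv")),
                         na = "NA")
      }
    }
    if (!is.null(suite$diagnosis)) {
      readr::write_csv(suite$diagnosis$points,
                       file.path(output_dir, paste0("roc_points_", tr, "_diagnosis.csv")),
                       na = "NA")
    }
  }
  if (length(roc_rows) > 0) {
    readr::write_csv(dplyr::bind_rows(roc_rows),
                     file.path(output_dir, "roc_summary.csv"), na = "NA")
  }
  summary_path <- file.path(output_dir, "summary.txt")
  con <- file(summary_path, open = "wt")
  on.exit(close(con))
  out <- function(...) writeLines(sprintf(...), con)
  out("Neuroplasticity-index analysis report")
  out("======================================")
  if (!is.null(report$pooled_baseline_correlation)) {
    pc <- report$pooled_baseline_correlation
    out("Pooled baseline BDNF vs HAMD-24: R^2 = %.3f, p = %.4g (n = %d)",
        pc$r_squared, pc$p_value, pc$n)
  }
  for (tr in names(report$roc)) {
    suite <- report$roc[[tr]]
    if (is.null(suite)) next
    if (!is.null(suite$diagnosis)) {
      opt <- youden_optimal(suite$diagnosis)
      out("%s diagnosis ROC (BDNF, patients vs controls): AUC = %.3f, sens %.1f%%, spec %.1f%%",
          tr, suite$diagnosis$auc, 100 * opt$sensitivity, 100 * opt$specificity)
    }
    for (arm in names(suite$prediction)) {
      pr <- suite$prediction[[arm]]
      if (inherits(pr, "roc_result")) {
        out("%s prediction ROC (%s, early NI enhancement): AUC = %.3f", tr, arm, pr$auc)
      } else {
        out("%s prediction ROC (%s): skipped (%s)", tr, arm, pr$reason)
      }
    }
  }
  if (length(report$errors) > 0) {
    out("Stages with errors: %s", paste(names(report$errors), collapse = ", "))
  }
  invisible(output_dir)
}

#' @export
print.ni_report <- function(x, ...) {
  cat("Neuroplasticity-index analysis report\n")
  if (!is.null(x$pooled_baseline_correlation)) {
    pc <- x$pooled_baseline_correlation
    cat(sprintf("  pooled baseline BDNF~HAMD: R^2 = %.3f, p = %.4g (n = %d)\n",
                pc$r_squared, pc$p_value, pc$n))
  }
  for (tr in names(x$roc)) {
    suite <- x$roc[[tr]]
    if (is.null(suite)) next
    if (!is.null(suite$diagnosis)) {
      cat(sprintf("  %s diagnosis AUC = %.3f\n", tr, suite$diagnosis$auc))
    }
    for (arm in names(suite$prediction)) {
      pr <- suite$prediction[[arm]]
      if (inherits(pr, "roc_result")) {
        cat(sprintf("  %s prediction AUC (%s) = %.3f\n", tr, arm, pr$auc))
      } else {
        cat(sprintf("  %s prediction (%s): skipped\n", tr, arm))
      }
    }
  }
  if (length(x$errors) > 0) {
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}
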