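#' Greenhouse--Geisser sphericity correction factor
#'
#' Estimates \eqn{\epsilon} from the sample covariance matrix of the
#' within-subject conditions. With \eqn{S^*} the double-centered covariance
#' (rows and columns centered),
#' \deqn{\hat\epsilon = \frac{(\mathrm{tr}\, S^*)^2}{(k-1)\sum_{ij} s^{*2}_{ij}},}
#' bounded in \eqn{[1/(k-1),\, 1]}. Under perfect sphericity (compound
#' symmetry) \eqn{\epsilon = 1}; a two-level factor is always spherical so
#' \eqn{k = 2} forces \eqn{\epsilon = 1} exactly.
#'
#' @param cov_mat Symmetric k x k sample covariance of the conditions,
#'   `k >= 2`.
#' @return The scalar \eqn{\hat\epsilon}.
#' @export
gg_epsilon <- function(cov_mat) {
  cov_mat <- as.matrix(cov_mat)
  k <- ncol(cov_mat)
  stopifnot(k >= 2, nrow(cov_mat) == k)
  if (max(abs(cov_mat - t(cov_mat))) > 1e-8 * max(1, max(abs(cov_mat)))) {
    rlang::abort("covariance matrix must be symmetric")
  }
  rm_ <- rowMeans(cov_mat)
  gm <- mean(cov_mat)
  sstar <- cov_mat - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + gm
  num <- sum(diag(sstar))^2
  den <- (k - 1) * sum(sstar^2)
  if (den == 0) return(1) # degenerate (e.g. zero between-condition variance)
  eps <- num / den
  min(1, max(1 / (k - 1), eps))
}

#' One-way repeated-measures ANOVA with Greenhouse--Geisser correction
#'
#' Partitions the total sum of squares of a complete subjects-by-conditions
#' matrix into subject, condition (time) and error components:
#' \deqn{SS_{time} = n\sum_j (\bar y_{\cdot j} - \bar y)^2,\quad
#'       SS_{subj} = k\sum_i (\bar y_{i\cdot} - \bar y)^2,\quad
#'       SS_{err} = SS_{tot} - SS_{subj} - SS_{time},}
#' \eqn{F = MS_{time}/MS_{err}} with raw df \eqn{(k-1,\,(n-1)(k-1))}.
#' Two p values are reported: `p_uncorrected` from the raw df (exact when
#' sphericity holds) and `p_gg` from the \eqn{\epsilon}-multiplied df, with
#' \eqn{\epsilon} estimated by [gg_epsilon()] from the sample covariance of
#' the conditions.
#'
#' @param data Numeric matrix, subjects in rows (n >= 2), conditions in
#'   columns (k >= 2), no missing cells (complete-case the data first).
#' @return An object of class `"rm_anova"`: list with `ss` (named numeric:
#'   subjects, time, error, total), `df` (named), `ms`, `f_stat`, `epsilon`,
#'   `df_corrected` (length-2), `p_uncorrected`, `p_gg`, `n`, `k`,
#'   `cond_means`.
#' @seealso [posthoc_vs_baseline()] for baseline contrasts,
#'   [mixed_anova()] for the split-plot design.
#' @export
rm_anova_oneway <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  stopifnot(n >= 2, k >= 2)
  if (anyNA(data)) rlang::abort("missing cells: complete-case the matrix first")
  grand <- mean(data)
  row_m <- rowMeans(data)
  col_m <- colMeans(data)
  ss_total <- sum((data - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_time <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_subj - ss_time
  df_time <- k - 1
  df_err <- (n - 1) * (k - 1)
  ms_time <- ss_time / df_time
  ms_err <- ss_err / df_err
  f_stat <- if (ms_err == 0) {
    if (ms_time == 0) 0 else Inf
  } else ms_time / ms_err
  eps <- gg_epsilon(stats::cov(data))
  p_unc <- stats::pf(f_stat, df_time, df_err, lower.tail = FALSE)
  p_gg <- stats::pf(f_stat, eps * df_time, eps * df_err, lower.tail = FALSE)
  structure(list(
    ss = c(subjects = ss_subj, time = ss_time, error = ss_err, total = ss_total),
    df = c(subjects = n - 1, time = df_time, error = df_err),
    ms = c(time = ms_time, error = ms_err),
    f_stat = f_stat, epsilon = eps,
    df_corrected = c(eps * df_time, eps * df_err),
    p_uncorrected = p_unc, p_gg = p_gg,
    n = n, k = k, cond_means = col_m
  ), class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf(
    "Repeated-measures ANOVA (n = %d subjects, k = %d conditions)\n", x$n, x$k))
  cat(sprintf("  time:  F(%d, %d) = %.3f, p = %.4g (uncorrected)\n",
              x$df[["time"]], x$df[["error"]], x$f_stat, x$p_uncorrected))
  cat(sprintf("  GG:    eps = %.3f, F(%.3f, %.2f), p = %.4g\n",
              x$epsilon, x$df_corrected[1], x$df_corrected[2], x$p_gg))
  invisible(x)
}

#' Split-plot (mixed drug-by-time) ANOVA
#'
#' Two-factor design with one between-subjects factor (treatment group) and
#' one within-subjects factor (visit), every subject measured at every
#' visit. The sums of squares decompose as between-subjects (group +
#' subjects-within-group) and within-subjects (time + group:time + error);
#' the group effect is tested against subjects-within-group, the time and
#' interaction effects against the within error, each of the latter two both
#' uncorrected and with the Greenhouse--Geisser \eqn{\epsilon} estimated
#' from the pooled within-group covariance of the visits.
#'
#' @param data Numeric matrix, subjects in rows, conditions (visits) in
#'   columns, complete.
#' @param group Vector of group labels, one per row; at least 2 groups with
#'   at least 2 subjects each.
#' @return An object of class `"mixed_anova"`: list with `effects` (a tibble
#'   with one row per effect: ss, df, ms, f_stat, p_uncorrected, and for
#'   within effects epsilon-corrected df and `p_gg`), `epsilon`, `ss_total`,
#'   `n`, `k`, `groups`, `cell_means`.
#' @export
mixed_anova <- function(data, group) {
  data <- as.matrix(data)
  if (anyNA(data)) rlang::abort("missing cells: complete-case the matrix first")
  group <- as.factor(group)
  stopifnot(length(group) == nrow(data))
  tab <- table(group)
  if (length(tab) < 2) rlang::abort("need at least 2 groups")
  if (any(tab < 2)) rlang::abort("every group needs at least 2 subjects")
  n <- nrow(data); k <- ncol(data); g <- length(tab)
  grand <- mean(data)
  subj_m <- rowMeans(data)
  col_m <- colMeans(data)
  grp_m <- tapply(subj_m, group, mean)
  ss_total <- sum((data - grand)^2)
  ss_between_subj <- k * sum((subj_m - grand)^2)
  ss_group <- k * sum(tab * (grp_m - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  # cell means: group x condition
  cell <- apply(data, 2, function(col) tapply(col, group, mean))
  ss_cells <- sum(rep(as.numeric(tab), times = k) * (as.numeric(cell) - grand)^2)
  ss_time <- n * sum((col_m - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_within <- ss_total - ss_between_subj
  ss_err <- ss_within - ss_time - ss_int
  df_group <- g - 1
  df_subj <- n - g
  df_time <- k - 1
  df_int <- (g - 1) * (k - 1)
  df_err <- (n - g) * (k - 1)
  # pooled within-group covariance of the conditions
  pooled <- matrix(0, k, k)
  for (lev in levels(group)) {
    rows <- data[group == lev, , drop = FALSE]
    pooled <- pooled + (nrow(rows) - 1) * stats::cov(rows)
  }
  pooled <- pooled / (n - g)
  eps <- gg_epsilon(pooled)
  fr <- function(ss, df, ms_err, df_err_) {
    ms <- ss / df
    f <- if (ms_err == 0) { if (ms == 0) 0 else Inf } else ms / ms_err
    list(ms = ms, f = f, p = stats::pf(f, df, df_err_, lower.tail = FALSE))
  }
  ms_subj <- ss_subj_within / df_subj
  ms_err <- ss_err / df_err
  e_group <- fr(ss_group, df_group, ms_subj, df_subj)
  e_time <- fr(ss_time, df_time, ms_err, df_err)
  e_int <- fr(ss_int, df_int, ms_err, df_err)
  p_gg_time <- stats::pf(e_time$f, eps * df_time, eps * df_err, lower.tail = FALSE)
  p_gg_int <- stats::pf(e_int$f, eps * df_int, eps * df_err, lower.tail = FALSE)
  effects <- tibble(
    effect = c("group", "subjects_within", "time", "group_time", "error"),
    ss = c(ss_group, ss_subj_within, ss_time, ss_int, ss_err),
    df = c(df_group, df_subj, df_time, df_int, df_err),
    ms = c(e_group$ms, ms_subj, e_time$ms, e_int$ms, ms_err),
    f_stat = c(e_group$f, NA, e_time$f, e_int$f, NA),
    p_uncorrected = c(e_group$p, NA, e_time$p, e_int$p, NA),
    df1_gg = c(NA, NA, eps * df_time, eps * df_int, NA),
    df2_gg = c(NA, NA, eps * df_err, eps * df_err, NA),
    p_gg = c(NA, NA, p_gg_time, p_gg_int, NA)
  )
  structure(list(effects = effects, epsilon = eps, ss_total = ss_total,
                 n = n, k = k, groups = levels(group), cell_means = cell),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(sprintf("Split-plot ANOVA (%d subjects, %d groups, %d conditions), GG eps = %.3f\n",
              x$n, length(x$groups), x$k, x$epsilon))
  eff <- x$effects[!is.na(x$effects$f_stat), ]
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-11s F = %8.3f, p = %.4g", eff$effect[i], eff$f_stat[i],
                eff$p_uncorrected[i]))
    if (!is.na(eff$p_gg[i])) cat(sprintf("  (GG p = %.4g)", eff$p_gg[i]))
    cat("\n")
  }
  invisible(x)
}
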