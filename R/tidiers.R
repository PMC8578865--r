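#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Pearson correlation result
#' @param x A `"pearson_cor"` object.
#' @param ... Unused.
#' @return One-row tibble `r, r_squared, t_stat, df, p_value, n`.
#' @export
tidy.pearson_cor <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r_squared, t_stat = x$t_stat,
         df = x$df, p_value = x$p_value, n = x$n)
}

#' @rdname tidy.pearson_cor
#' @export
glance.pearson_cor <- tidy.pearson_cor

#' Tidy a Welch t-test result
#' @param x A `"welch_t"` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.welch_t <- function(x, ...) {
  tibble(t_stat = x$t_stat, df = x$df, p_value = x$p_value,
         mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a repeated-measures ANOVA
#'
#' One row per effect with sums of squares, raw df, the
#' Greenhouse--Geisser epsilon and corrected df for the within effect, F and
#' both p values — the tidy export schema `effect, ss, df_raw, epsilon,
#' df1_corrected, df2_corrected, f_stat, p_uncorrected, p_gg`.
#'
#' @param x An `"rm_anova"` object.
#' @param ... Unused.
#' @return A tibble with rows `subjects`, `time`, `error`.
#' @export
tidy.rm_anova <- function(x, ...) {
  tibble(
    effect = c("subjects", "time", "error"),
    ss = unname(x$ss[c("subjects", "time", "error")]),
    df_raw = unname(x$df[c("subjects", "time", "error")]),
    epsilon = c(NA, x$epsilon, NA),
    df1_corrected = c(NA, x$df_corrected[1], NA),
    df2_corrected = c(NA, x$df_corrected[2], NA),
    f_stat = c(NA, x$f_stat, NA),
    p_uncorrected = c(NA, x$p_uncorrected, NA),
    p_gg = c(NA, x$p_gg, NA)
  )
}

#' @rdname tidy.rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(f_stat = x$f_stat, epsilon = x$epsilon,
         df1 = x$df_corrected[1], df2 = x$df_corrected[2],
         p_uncorrected = x$p_uncorrected, p_gg = x$p_gg, n = x$n, k = x$k)
}

#' Tidy a split-plot ANOVA
#' @param x A `"mixed_anova"` object.
#' @param ... Unused.
#' @return The effects tibble (one row per effect).
#' @export
tidy.mixed_anova <- function(x, ...) x$effects

#' @rdname tidy.mixed_anova
#' @export
glance.mixed_anova <- function(x, ...) {
  eff <- x$effects
  pick <- function(e, col) eff[[col]][eff$effect == e]
  tibble(f_group = pick("group", "f_stat"),
         p_group = pick("group", "p_uncorrected"),
         f_time = pick("time", "f_stat"),
         p_time_gg = pick("time", "p_gg"),
         f_interaction = pick("group_time", "f_stat"),
         p_interaction_gg = pick("group_time", "p_gg"),
         epsilon = x$epsilon, n = x$n, k = x$k)
}

#' Tidy an ROC result
#' @param x A `"roc_result"` object.
#' @param ... Unused.
#' @return The operating-point tibble `threshold, sensitivity, specificity`.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  opt <- youden_optimal(x)
  tibble(auc = x$auc, optimal_threshold = opt$threshold,
         sensitivity = opt$sensitivity, specificity = opt$specificity,
         youden_j = opt$youden_j, n_pos = x$n_pos, n_neg = x$n_neg,
         orientation = x$orientation)
}
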