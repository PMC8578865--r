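#' Pearson correlation with significance, from first principles
#'
#' Computes the Pearson product-moment correlation on raw values, its
#' coefficient of determination, and a two-tailed p value from the exact
#' small-sample t reference distribution:
#' \deqn{r = \frac{\sum (x-\bar x)(y-\bar y)}
#'               {\sqrt{\sum (x-\bar x)^2 \sum (y-\bar y)^2}}, \qquad
#'       t = r\sqrt{\frac{n-2}{1-r^2}},}
#' with \eqn{t} referred to Student's t on \eqn{n-2} degrees of freedom.
#' When \eqn{r = \pm 1} the statistic is infinite and the p value is 0.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#'   Pairs with a missing value in either vector are dropped first.
#' @return An object of class `"pearson_cor"`: a list with `r`, `r_squared`,
#'   `t_stat`, `df`, `p_value` (two-tailed), `n`.
#' @seealso [generics::tidy()] and [generics::glance()] methods are provided.
#' @export
#' @examples
#' pearson_test(c(1, 2, 3), c(1, 3, 2))$r # 0.5
pearson_test <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) rlang::abort("need at least 3 complete pairs")
  cx <- x - mean(x); cy <- y - mean(y)
  ssx <- sum(cx^2); ssy <- sum(cy^2)
  if (ssx == 0 || ssy == 0) rlang::abort("correlation undefined for a constant vector")
  r <- sum(cx * cy) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (abs(r) >= 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(r = r, r_squared = r^2, t_stat = t_stat, df = df,
                 p_value = p, n = n),
            class = "pearson_cor")
}

#' @export
print.pearson_cor <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (R^2 = %.4f), t(%d) = %.3f, p = %.4g, n = %d\n",
              x$r, x$r_squared, x$df, x$t_stat, x$p_value, x$n))
  invisible(x)
}

#' Welch two-sample t test, from first principles
#'
#' Unequal-variance (Welch) t statistic with Welch--Satterthwaite degrees of
#' freedom and a two-tailed p value. Used for cross-sectional contrasts such
#' as patients versus healthy controls. If both samples have zero variance
#' and equal means the statistic is 0 with p = 1 by convention.
#'
#' @param a,b Numeric vectors, each of length at least 2 (missing values
#'   dropped).
#' @return An object of class `"welch_t"`: list with `t_stat`, `df`,
#'   `p_value`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) rlang::abort("each sample needs n >= 2")
  na <- length(a); nb <- length(b)
  va <- stats::var(a) / na; vb <- stats::var(b) / nb
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    df <- na + nb - 2
    p <- if (d == 0) 1 else 0
  } else {
    t_stat <- d / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(t_stat = t_stat, df = df, p_value = p,
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t test: t(%.2f) = %.3f, p = %.4g (means %.3f vs %.3f)\n",
              x$df, x$t_stat, x$p_value, x$mean_a, x$mean_b))
  invisible(x)
}

#' Paired t test of each condition against a baseline column
#'
#' Post-hoc contrasts for a repeated-measures design: every non-baseline
#' column of the subjects-by-conditions matrix is compared to the baseline
#' column with a paired t test. If the paired differences have zero variance
#' the statistic degenerates: t = 0 and p = 1 when all differences are zero,
#' otherwise t is infinite (with sign) and p = 0; both cases are returned
#' as-is and flagged in the `degenerate` column.
#'
#' @param data Numeric matrix, subjects in rows, conditions (e.g. visit
#'   days) in columns; complete cases only.
#' @param baseline_index Column index of the baseline condition (default 1).
#' @param correction Multiplicity correction for the contrast family:
#'   `"none"` (default) or `"bonferroni"`.
#' @return A tibble `condition, mean_diff, t_stat, df, p_value, p_adjusted,
#'   degenerate`, one row per non-baseline column.
#' @export
posthoc_vs_baseline <- function(data, baseline_index = 1L,
                                correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  data <- as.matrix(data)
  k <- ncol(data)
  stopifnot(k >= 2, baseline_index >= 1, baseline_index <= k,
            !anyNA(data))
  base <- data[, baseline_index]
  idx <- setdiff(seq_len(k), baseline_index)
  rows <- lapply(idx, function(j) {
    d <- data[, j] - base
    n <- length(d)
    sd_d <- stats::sd(d)
    if (sd_d == 0) {
      t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
      degen <- TRUE
    } else {
      t_stat <- mean(d) / (sd_d / sqrt(n))
      p <- 2 * stats::pt(-abs(t_stat), n - 1)
      degen <- FALSE
    }
    tibble(condition = colnames(data)[j] %||% as.character(j),
           mean_diff = mean(d), t_stat = t_stat, df = n - 1L,
           p_value = p, degenerate = degen)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- switch(correction,
    none = out$p_value,
    bonferroni = pmin(1, out$p_value * nrow(out))
  )
  out[, c("condition", "mean_diff", "t_stat", "df", "p_value", "p_adjusted",
          "degenerate")]
}
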