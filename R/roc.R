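#' Empirical ROC curve with trapezoidal AUC
#'
#' Builds the full ROC staircase over thresholds placed at the distinct
#' score values, and integrates the area under the curve trapezoidally.
#' Trapezoidal integration credits tied scores with one half, so the AUC
#' equals the pair-counting (Mann--Whitney) statistic: the probability that
#' a random positive outranks a random negative, ties counted 1/2. For
#' markers where the positive class has *lower* values (e.g. serum BDNF in
#' depression versus healthy controls), use
#' `orientation = "lower_is_positive"`; scores are negated internally and
#' thresholds reported on the original scale.
#'
#' @param scores Numeric vector of marker values, no missing values.
#' @param labels Binary vector (logical, or 0/1) of the same length; `TRUE`/1
#'   is the positive class. Both classes must be present.
#' @param orientation `"higher_is_positive"` (default) or
#'   `"lower_is_positive"`.
#' @return An object of class `"roc_result"`: list with `points` (tibble
#'   `threshold, sensitivity, specificity`, one row per operating point,
#'   ordered from no positives called to all called), `auc`, `n_pos`,
#'   `n_neg`, `orientation`. Predicted positive means oriented score >=
#'   threshold.
#' @seealso [auc_pair_counting()] (the definitional oracle),
#'   [youden_optimal()].
#' @export
roc_curve <- function(scores, labels,
                      orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  if (anyNA(scores) || anyNA(labels)) rlang::abort("missing scores or labels")
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) rlang::abort("both classes must be present")
  s <- if (orientation == "lower_is_positive") -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(s[labels] >= t) / n_pos, numeric(1))
  spec <- vapply(thr, function(t) sum(s[!labels] < t) / n_neg, numeric(1))
  # leading point where nothing is called positive
  points <- tibble(
    threshold = c(Inf, thr),
    sensitivity = c(0, sens),
    specificity = c(1, spec)
  )
  fpr <- 1 - points$specificity
  auc <- sum(diff(fpr) * (utils::head(points$sensitivity, -1) +
                            utils::tail(points$sensitivity, -1)) / 2)
  if (orientation == "lower_is_positive") {
    points$threshold <- -points$threshold
  }
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 orientation = orientation),
            class = "roc_result")
}

#' AUC by exhaustive pair counting
#'
#' The definitional Mann--Whitney estimate: over all positive-negative
#' pairs, the fraction in which the positive scores higher, ties counted
#' one half. Serves as the independent oracle for [roc_curve()]'s
#' trapezoidal AUC, to which it is equal by construction.
#'
#' @inheritParams roc_curve
#' @return The AUC as a scalar in \[0, 1\].
#' @export
auc_pair_counting <- function(scores, labels,
                              orientation = c("higher_is_positive", "lower_is_positive")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) rlang::abort("both classes must be present")
  s <- if (orientation == "lower_is_positive") -scores else scores
  pos <- s[labels]; neg <- s[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  sum(cmp) / (length(pos) * length(neg))
}

#' Youden-optimal operating point
#'
#' Selects the threshold maximizing Youden's J = sensitivity + specificity
#' - 1. Ties are broken in favour of higher sensitivity, then of the
#' threshold calling more cases positive (lower oriented threshold). The
#' operating-point rule is an assumption of this package (common clinical
#' practice); `closest_topleft` (minimal distance to the (0,1) corner) is
#' available as an alternative.
#'
#' @param roc A `"roc_result"` from [roc_curve()].
#' @param method `"youden"` (default) or `"closest_topleft"`.
#' @return A one-row tibble `threshold, sensitivity, specificity, youden_j`.
#' @export
youden_optimal <- function(roc, method = c("youden", "closest_topleft")) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "roc_result"))
  pts <- roc$points
  # skip the degenerate all-negative sentinel unless it is the only point
  crit <- switch(method,
    youden = pts$sensitivity + pts$specificity - 1,
    closest_topleft = -((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  )
  ord <- order(-crit, -pts$sensitivity,
               if (roc$orientation == "lower_is_positive") -pts$threshold else pts$threshold,
               decreasing = FALSE)
  best <- pts[ord[1], ]
  tibble(threshold = best$threshold,
         sensitivity = best$sensitivity,
         specificity = best$specificity,
         youden_j = best$sensitivity + best$specificity - 1)
}

#' @export
print.roc_result <- function(x, ...) {
  opt <- youden_optimal(x)
  cat(sprintf("ROC (%s): AUC = %.4f (%d positives, %d negatives)\n",
              x$orientation, x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden-optimal threshold %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              opt$threshold, 100 * opt$sensitivity, 100 * opt$specificity))
  invisible(x)
}

#' Percentile bootstrap confidence interval for an AUC
#'
#' Optional seeded percentile bootstrap over subjects (stratified by class).
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed for reproducibility.
#' @return Named numeric: `lower`, `upper`.
#' @export
auc_bootstrap_ci <- function(scores, labels, orientation = "higher_is_positive",
                             n_boot = 2000, conf = 0.95, seed = 1L) {
  labels <- as.logical(labels)
  pos_i <- which(labels); neg_i <- which(!labels)
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos_i, replace = TRUE), sample(neg_i, replace = TRUE))
    auc_pair_counting(scores[i], labels[i], orientation)
  }, numeric(1))
  a <- (1 - conf) / 2
  stats::quantile(aucs, c(a, 1 - a), names = FALSE) |>
    stats::setNames(c("lower", "upper"))
}
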