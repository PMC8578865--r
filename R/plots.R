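#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_abline labs
#'   theme_minimal autoplot geom_errorbar position_dodge coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot an ROC curve
#'
#' @param object A `"roc_result"` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot: sensitivity against 1 - specificity with the chance
#'   diagonal and the Youden-optimal point highlighted.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  opt <- youden_optimal(object)
  ggplot(pts, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(linewidth = 0.7) +
    geom_point(data = opt, colour = "red", size = 2) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC, AUC = %.3f", object$auc)) +
    theme_minimal()
}

#' Plot a repeated-measures time course
#'
#' Mean and standard error per visit for one measure and arm.
#'
#' @param object A `"timecourse_result"` from [run_symptom_timecourse()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.timecourse_result <- function(object, ...) {
  df <- tibble(day = object$days, mean = unname(object$anova$cond_means))
  ggplot(df, aes(x = .data$day, y = .data$mean)) +
    geom_line() + geom_point() +
    labs(x = "Day", y = object$measure,
         title = sprintf("%s time course, %s arm (n = %d)",
                         object$measure, object$arm, object$n)) +
    theme_minimal()
}

#' Mean trajectories of a measure per arm
#'
#' Convenience plot of group means with standard errors over visits, for
#' any measurement column of a trial tibble.
#'
#' @param data A validated trial tibble.
#' @param measure Measurement column (default `"hamd24"`).
#' @return A ggplot.
#' @export
plot_trajectories <- function(data, measure = "hamd24") {
  stopifnot(measure %in% MEASURE_VARS)
  df <- data[data$arm != "healthy_control" & !is.na(data[[measure]]), ]
  agg <- df |>
    dplyr::group_by(.data$arm, .data$day) |>
    dplyr::summarise(
      mean = mean(.data[[measure]]),
      se = stats::sd(.data[[measure]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot(agg, aes(x = .data$day, y = .data$mean, colour = .data$arm)) +
    geom_line() + geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
                  width = 0.6) +
    labs(x = "Day", y = measure) +
    theme_minimal()
}
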