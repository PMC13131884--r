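# Diagnostic plots.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_point
#'   geom_errorbar geom_col labs theme_minimal facet_wrap
NULL

#' Plot a recording with optional step annotations
#'
#' Forefoot, heel and midfoot traces against time, with heel-strike
#' (solid) and toe-off (dashed) markers when a step table is supplied —
#' the standard visual check that segmentation delineates stance phases
#' correctly.
#'
#' @param object A [grf_recording()].
#' @param steps Optional `grf_steps` tibble from [segment_steps()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grf_recording <- function(object, steps = NULL, ...) {
  df <- tidyr::pivot_longer(object, c("heel_n", "midfoot_n", "forefoot_n"),
                            names_to = "channel", values_to = "force")
  df$channel <- factor(df$channel, c("forefoot_n", "midfoot_n", "heel_n"),
                       c("forefoot", "midfoot", "heel"))
  m <- recording_meta(object)
  p <- ggplot(df, aes(x = .data$time_s, y = .data$force,
                      colour = .data$channel)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)",
         y = if (m$normalized) "force (BW)" else "force (N)",
         colour = NULL,
         title = sprintf("%s | %.1f m/s, %g deg", m$subject_id, m$speed_mps,
                         m$incline_deg)) +
    theme_minimal()
  if (!is.null(steps) && nrow(steps)) {
    p <- p +
      geom_vline(xintercept = steps$start_s, linetype = 1, alpha = 0.35) +
      geom_vline(xintercept = steps$end_s, linetype = 2, alpha = 0.35)
  }
  p
}

#' Plot the cross-validation curve of a feature selection
#'
#' Mean CV accuracy against the candidate number of features K, with
#' one-standard-error bars and the chosen K highlighted.
#'
#' @param object A `selection_result` from [select_features()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tibble::tibble(k = object$k_grid, mean = object$cv_mean,
                       se = object$cv_se)
  ggplot(df, aes(x = .data$k, y = .data$mean)) +
    geom_line() +
    geom_errorbar(aes(ymin = .data$mean - .data$se,
                      ymax = .data$mean + .data$se), width = 0.02) +
    geom_point(data = df[df$k == object$chosen_k, ], colour = "red",
               size = 3) +
    labs(x = "number of features K", y = "cross-validated accuracy",
         title = sprintf("one-standard-error rule: K = %d", object$chosen_k)) +
    theme_minimal()
}

#' Plot per-subject top-k accuracies of a cohort run
#'
#' @param object A `cohort_result` from [run_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_result <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$reports[, c("subject_id", "top1", "top2", "top3")],
    c("top1", "top2", "top3"), names_to = "metric", values_to = "accuracy")
  ggplot(df, aes(x = .data$subject_id, y = .data$accuracy,
                 fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "accuracy", fill = NULL) +
    theme_minimal()
}
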