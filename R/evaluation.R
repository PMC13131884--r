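# Top-k accuracy, weighted precision/recall, chance accuracy, and
# cohort-level aggregation of per-subject reports.

#' Top-k accuracy
#'
#' Fraction of rows whose true class code appears within the first `k`
#' columns of the ranking matrix (classes in decreasing predicted
#' probability). `k` larger than the number of ranked classes is clamped.
#'
#' @param true_codes True class codes.
#' @param rankings Matrix of ranked class codes from [predict_ranked()].
#' @param k Rank depth (>= 1).
#' @return Fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(true_codes, rankings, k) {
  rankings <- as.matrix(rankings)
  stopifnot(k >= 1, length(true_codes) == nrow(rankings))
  k <- min(k, ncol(rankings))
  hit <- vapply(seq_along(true_codes),
                function(i) true_codes[i] %in% rankings[i, seq_len(k)],
                logical(1))
  mean(hit)
}

#' Weighted-average precision and recall
#'
#' Per-class precision and recall averaged with weights proportional to
#' each class's support in the true labels. Classes never predicted
#' contribute precision 0; weighted recall equals overall (top-1)
#' accuracy.
#'
#' @param true_codes True class codes.
#' @param pred_codes Predicted (rank-1) class codes, same length.
#' @return A one-row tibble with `precision_w` and `recall_w`.
#' @export
weighted_precision_recall <- function(true_codes, pred_codes) {
  stopifnot(length(true_codes) == length(pred_codes), length(true_codes) >= 1)
  classes <- sort(unique(c(true_codes, pred_codes)))
  tc <- factor(true_codes, levels = classes)
  pc <- factor(pred_codes, levels = classes)
  cm <- table(tc, pc)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  precision <- ifelse(pred_n == 0, 0, tp / pred_n)
  recall <- ifelse(true_n == 0, 0, tp / true_n)
  w <- true_n / sum(true_n)
  tibble::tibble(precision_w = sum(w * precision), recall_w = sum(w * recall))
}

#' Chance accuracy of uniform random guessing
#'
#' @param n_classes Number of classes (>= 1).
#' @return `1 / n_classes`.
#' @export
chance_accuracy <- function(n_classes) {
  stopifnot(n_classes >= 1)
  1 / n_classes
}

#' Aggregate per-subject reports into cohort summaries
#'
#' Computes, per metric column, the arithmetic mean, the median (midpoint
#' of the middle pair for even cohort sizes) and the population standard
#' deviation (divide by n) across subjects.
#'
#' @param reports A data frame of per-subject metrics, e.g. rows of
#'   [run_subject()] reports or [reference_cohort_metrics()].
#' @param metrics Metric columns to summarize (default every numeric
#'   column except `subject`).
#' @return A tibble of class `cohort_summary` with columns `metric`,
#'   `mean`, `median`, `sd`.
#' @export
summarize_cohort <- function(reports, metrics = NULL) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  if (is.null(metrics)) {
    metrics <- names(reports)[vapply(reports, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("subject", "subject_no", "seed"))
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- purrr::map_dfr(metrics, function(mcol) {
    x <- reports[[mcol]]
    tibble::tibble(metric = mcol, mean = mean(x),
                   median = stats::median(x), sd = pop_sd(x))
  })
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Render a cohort performance table
#'
#' Per-subject rows plus an `Average` row, with metrics rounded to three
#' decimals and sample sizes displayed as integers (half-up rounding for
#' the average).
#'
#' @param reports A data frame with a subject identifier column
#'   (`subject_id` or `subject`), a `sample_size` column, and metric
#'   columns.
#' @return A tibble: the per-subject rows followed by the `Average` row.
#' @export
render_cohort_table <- function(reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  id_col <- intersect(c("subject_id", "subject"), names(reports))[1]
  if (is.na(id_col)) rlang::abort("no subject identifier column found")
  metric_cols <- setdiff(names(reports)[vapply(reports, is.numeric, logical(1))],
                         c("sample_size", "seed", id_col))
  body <- tibble::tibble(subject = as.character(reports[[id_col]]))
  if ("sample_size" %in% names(reports)) {
    body$sample_size <- as.integer(reports$sample_size)
  }
  for (mc in metric_cols) body[[mc]] <- round(reports[[mc]], 3)
  avg <- tibble::tibble(subject = "Average")
  if ("sample_size" %in% names(reports)) {
    avg$sample_size <- as.integer(floor(mean(reports$sample_size) + 0.5))
  }
  for (mc in metric_cols) avg[[mc]] <- round(mean(reports[[mc]]), 3)
  dplyr::bind_rows(body, avg)
}

#' Published per-subject reference metrics
#'
#' The per-subject performance table of the original 14-subject treadmill
#' study (sample sizes and Top-1/2/3 accuracy, weighted precision and
#' recall of each subject-specific 18-condition model), shipped as a
#' plain-text fixture so its printed cohort aggregates can be recomputed.
#'
#' @return A tibble with columns `subject`, `sample_size`, `top1`, `top2`,
#'   `top3`, `precision`, `recall`.
#' @export
reference_cohort_metrics <- function() {
  path <- system.file("extdata", "reference_cohort_metrics.csv",
                      package = "grfstep", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Recompute the reference cohort aggregates
#'
#' Applies [summarize_cohort()] to [reference_cohort_metrics()]: mean,
#' median and population SD of each published per-subject metric, plus the
#' mean sample size.
#'
#' @return A `cohort_summary` tibble.
#' @export
reference_cohort_aggregates <- function() {
  summarize_cohort(reference_cohort_metrics(),
                   metrics = c("sample_size", "top1", "top2", "top3",
                               "precision", "recall"))
}
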