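# End-to-end orchestration: parse -> features -> select -> train -> evaluate
# per subject, and cohort-level aggregation.

#' Pipeline configuration
#'
#' Bundles the stage configurations and the master seed for a full
#' subject/cohort run.
#'
#' @param parser A [parser_config()].
#' @param bank A [feature_bank()].
#' @param include_total Also featurize the total-foot channel
#'   (default `FALSE`).
#' @param cor_threshold Correlation-pruning threshold (default 0.8).
#' @param k_grid Candidate K values for the one-standard-error rule.
#' @param select_folds CV folds for the K choice (default 5).
#' @param tree_folds CV folds for single-feature trees (default 3).
#' @param test_fraction Held-out fraction per class (default 0.2).
#' @param n_trees Random Forest size (default 100).
#' @param tasks Tasks to run: subset of `"combined"`, `"speed"`,
#'   `"incline"`.
#' @param master_seed Master integer seed; per-subject seeds are derived
#'   from it by subject index.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(parser = parser_config(),
                            bank = feature_bank(),
                            include_total = FALSE,
                            cor_threshold = 0.8,
                            k_grid = c(5, 10, 15, 20, 30, 40, 50, 75, 100),
                            select_folds = 5, tree_folds = 3,
                            test_fraction = 0.2, n_trees = 100,
                            tasks = c("combined", "speed", "incline"),
                            master_seed = 1) {
  stopifnot(all(tasks %in% c("combined", "speed", "incline")),
            "combined" %in% tasks)
  structure(list(parser = parser, bank = bank,
                 include_total = include_total,
                 cor_threshold = cor_threshold, k_grid = k_grid,
                 select_folds = select_folds, tree_folds = tree_folds,
                 test_fraction = test_fraction, n_trees = n_trees,
                 tasks = tasks, master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full pipeline for one subject
#'
#' Parses every recording into steps, encodes condition labels, splits
#' 80/20 stratified by condition, zero-pads and min-max scales the steps
#' (scaler fitted on training rows only), extracts the feature bank, drops
#' invalid features (judged on training rows), runs two-stage feature
#' selection on the training rows, trains the combined-task Random Forest,
#' and evaluates ranked predictions on the held-out steps; the speed-only
#' and incline-only tasks re-use the same features and partition.
#'
#' @param recordings List of [grf_recording()]s (one per condition).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for this subject (default the config's master
#'   seed).
#' @param subject_id Subject identifier (default: from the first
#'   recording).
#' @return An object of class `subject_fit`: list with `report` (one-row
#'   tibble of metrics), `selection` (the `selection_result`), `models`,
#'   `rankings`, `encoder`, `steps`, `features` and the evaluation
#'   `test_truth`.
#' @export
run_subject <- function(recordings, config = pipeline_config(),
                        seed = config$master_seed, subject_id = NULL) {
  stopifnot(length(recordings) >= 1)
  if (is.null(subject_id)) subject_id <- attr(recordings[[1]], "subject_id")
  seed <- as.integer(seed) %% 2147483647L

  steps <- segment_session(recordings, config$parser)
  if (nrow(steps) < 10) rlang::abort("too few parsed steps to model")
  conditions <- steps[, c("speed_mps", "incline_deg")]
  expected <- length(recordings)
  seen <- nrow(dplyr::distinct(conditions))
  if (seen < expected) {
    rlang::warn(sprintf("subject %s: only %d of %d conditions yielded steps",
                        subject_id, seen, expected))
  }
  encoder <- condition_encoder(conditions)
  codes <- encode_conditions(conditions, encoder)

  is_train <- split_train_test(codes, config$test_fraction, seed = seed)

  padded <- pad_steps(steps)
  scaler <- fit_minmax(padded, is_train)
  scaled <- apply_minmax(scaler, padded)
  feats <- extract_features(scaled, bank = config$bank,
                            include_total = config$include_total)
  feats <- drop_invalid_features(feats, rows = is_train)
  feat_cols <- setdiff(names(feats), "step_id")
  X <- as.matrix(feats[feat_cols])

  sel <- select_features(X[is_train, , drop = FALSE], codes[is_train],
                         cor_threshold = config$cor_threshold,
                         k_grid = config$k_grid, folds = config$select_folds,
                         tree_folds = config$tree_folds, seed = seed + 1L,
                         n_trees = config$n_trees)

  model <- train_grf_model(X[is_train, sel$selected, drop = FALSE],
                           codes[is_train], classes = encoder$code,
                           n_trees = config$n_trees, seed = seed + 2L)
  rankings <- predict_ranked(model, X[!is_train, , drop = FALSE])
  truth <- codes[!is_train]
  pr <- weighted_precision_recall(truth, rankings[, 1])

  report <- tibble::tibble(
    subject_id = subject_id,
    sample_size = nrow(steps),
    n_train = sum(is_train), n_test = sum(!is_train),
    n_classes = nrow(encoder),
    chosen_k = sel$chosen_k,
    top1 = topk_accuracy(truth, rankings, 1),
    top2 = topk_accuracy(truth, rankings, 2),
    top3 = topk_accuracy(truth, rankings, 3),
    precision_w = pr$precision_w,
    recall_w = pr$recall_w)

  models <- list(combined = model)
  axis_rankings <- list()
  for (axis in intersect(config$tasks, c("speed", "incline"))) {
    ax <- retrain_axis(X, conditions, is_train, sel$selected, axis = axis,
                       n_trees = config$n_trees, seed = seed + 3L)
    report[[paste0(axis, "_top1")]] <- ax$metrics$top1
    report[[paste0(axis, "_n_classes")]] <- ax$metrics$n_classes
    models[[axis]] <- ax$model
    axis_rankings[[axis]] <- ax$rankings
  }

  structure(list(report = report, selection = sel, models = models,
                 rankings = c(list(combined = rankings), axis_rankings),
                 encoder = encoder, steps = steps, is_train = is_train,
                 test_truth = truth, scaler = scaler, seed = seed),
            class = "subject_fit")
}

#' @export
print.subject_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<subject_fit> %s: %d steps, %d classes | top-1 %.3f, top-2 %.3f, top-3 %.3f (K = %d)\n",
              r$subject_id, r$sample_size, r$n_classes, r$top1, r$top2,
              r$top3, r$chosen_k))
  invisible(x)
}

#' Tidy a subject fit
#'
#' @param x A `subject_fit`.
#' @param ... Unused.
#' @return The one-row per-subject report tibble.
#' @export
tidy.subject_fit <- function(x, ...) x$report

#' Run the pipeline for a whole cohort
#'
#' Applies [run_subject()] independently to each subject (per-subject seed
#' = `master_seed + subject index`), isolating failures: a subject whose
#' run errors is dropped with a warning and does not affect the others.
#'
#' @param cohort A `grf_cohort` tibble from [simulate_cohort()], or a list
#'   of per-subject recording lists.
#' @param config A [pipeline_config()].
#' @param keep_fits Keep the full per-subject fits (default `FALSE`; the
#'   reports are always kept).
#' @return An object of class `cohort_result`: list with `reports` (tibble,
#'   one row per subject), `summary` ([summarize_cohort()]), `table`
#'   ([render_cohort_table()]), and optionally `fits`.
#' @export
run_cohort <- function(cohort, config = pipeline_config(), keep_fits = FALSE) {
  rec_lists <- if (is.data.frame(cohort)) cohort$recordings else cohort
  ids <- if (is.data.frame(cohort) && "subject_id" %in% names(cohort)) {
    cohort$subject_id
  } else {
    sprintf("S%02d", seq_along(rec_lists))
  }
  fits <- vector("list", length(rec_lists))
  reports <- vector("list", length(rec_lists))
  for (s in seq_along(rec_lists)) {
    fit <- tryCatch(
      run_subject(rec_lists[[s]], config,
                  seed = config$master_seed + 1000L * s,
                  subject_id = ids[s]),
      error = function(e) {
        rlang::warn(sprintf("subject %s failed and was skipped: %s",
                            ids[s], conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) {
      reports[[s]] <- fit$report
      if (keep_fits) fits[[s]] <- fit
    }
  }
  reports <- dplyr::bind_rows(reports)
  if (nrow(reports) == 0) rlang::abort("every subject failed")
  metric_cols <- intersect(c("sample_size", "top1", "top2", "top3",
                             "precision_w", "recall_w", "speed_top1",
                             "incline_top1"), names(reports))
  out <- list(reports = reports,
              summary = summarize_cohort(reports, metrics = metric_cols),
              table = render_cohort_table(reports))
  if (keep_fits) out$fits <- fits
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d subjects\n", nrow(x$reports)))
  print(x$table)
  invisible(x)
}

#' Tidy a cohort result
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return The per-subject report tibble.
#' @export
tidy.cohort_result <- function(x, ...) x$reports

#' One-row cohort summary
#'
#' @param x A `cohort_result`.
#' @param ... Unused.
#' @return A one-row tibble with cohort mean top-1/2/3, weighted
#'   precision/recall, and (when run) the single-axis accuracies.
#' @export
glance.cohort_result <- function(x, ...) {
  s <- x$summary
  grab <- function(m) if (m %in% s$metric) s$mean[s$metric == m] else NA_real_
  tibble::tibble(n_subjects = nrow(x$reports),
                 top1_mean = grab("top1"), top2_mean = grab("top2"),
                 top3_mean = grab("top3"),
                 precision_w_mean = grab("precision_w"),
                 recall_w_mean = grab("recall_w"),
                 speed_top1_mean = grab("speed_top1"),
                 incline_top1_mean = grab("incline_top1"))
}
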