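# Per-subject model training: stratified 80/20 split, Random Forest on the
# selected features, ranked-probability prediction, and the speed-only /
# incline-only re-projection experiments.

#' Stratified train/test split
#'
#' Randomly assigns `test_fraction` of the rows of each class to the test
#' partition (rounded per class), guaranteeing every class is represented
#' in training; single-row classes go to training with a warning.
#'
#' @param labels Class labels (one per row).
#' @param test_fraction Fraction of each class reserved for testing
#'   (default 0.2).
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` for training rows.
#' @export
split_train_test <- function(labels, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction >= 0, test_fraction < 1)
  is_train <- rep(TRUE, length(labels))
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) == 1) {
        rlang::warn(sprintf("class %s has a single row; assigned to training",
                            format(cl)))
        next
      }
      n_test <- min(round(length(idx) * test_fraction), length(idx) - 1L)
      if (n_test > 0) {
        is_train[sample(idx, n_test)] <- FALSE
      }
    }
  })
  is_train
}

#' Project combined condition labels onto one axis
#'
#' Reduces (speed, incline) condition labels to their speed component
#' (3 classes on the standard grid) or incline component (6 classes), for
#' the single-axis re-training experiments.
#'
#' @param conditions A data frame with `speed_mps` and `incline_deg`.
#' @param axis `"speed"` or `"incline"`.
#' @return Numeric vector of axis values (one per row).
#' @export
project_labels <- function(conditions, axis = c("speed", "incline")) {
  axis <- match.arg(axis)
  if (axis == "speed") conditions$speed_mps else conditions$incline_deg
}

#' Train a Random Forest loading-condition classifier
#'
#' @param X Numeric feature matrix (training rows x selected features).
#' @param y Integer class codes (or any labels); the factor level set can
#'   be fixed via `classes` so prediction covers classes absent from
#'   training.
#' @param classes Full ordered class set (default the sorted unique labels).
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for the forest's bootstrap/feature sampling.
#' @return An object of class `grf_model` wrapping the fitted forest with
#'   its class set, seed, and training accuracy.
#' @export
train_grf_model <- function(X, y, classes = sort(unique(y)), n_trees = 100,
                            seed = 1) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) rlang::abort("training requires at least two classes")
  yf <- factor(y, levels = classes)
  fit <- withr::with_seed(as.integer(seed) %% 2147483647L, {
    randomForest::randomForest(x = X, y = yf, ntree = n_trees)
  })
  structure(list(forest = fit, classes = classes,
                 features = colnames(X), n_trees = n_trees, seed = seed,
                 train_accuracy = mean(predict(fit, X) == yf)),
            class = "grf_model")
}

#' @export
print.grf_model <- function(x, ...) {
  cat(sprintf("<grf_model> Random Forest, %d trees, %d classes, %d features (train accuracy %.3f)\n",
              x$n_trees, length(x$classes), length(x$features),
              x$train_accuracy))
  invisible(x)
}

#' One-row summary of a fitted model
#'
#' @param x A `grf_model`.
#' @param ... Unused.
#' @return A one-row tibble with tree count, class count, feature count,
#'   training accuracy and out-of-bag error.
#' @export
glance.grf_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, n_classes = length(x$classes),
                 n_features = length(x$features),
                 train_accuracy = x$train_accuracy,
                 oob_error = tail(x$forest$err.rate[, "OOB"], 1))
}

#' Rank classes by predicted probability
#'
#' Produces, for each row of a probability matrix, the full class ranking
#' in decreasing probability; ties are broken by ascending class code so
#' rankings (and hence top-k accuracy) are deterministic.
#'
#' @param prob Matrix of class probabilities (rows x classes, columns in
#'   the order of `classes`).
#' @param classes Class codes corresponding to the columns.
#' @return Integer-ish matrix of ranked class codes (rows x classes).
#' @export
rank_probabilities <- function(prob, classes) {
  stopifnot(ncol(prob) == length(classes))
  ordc <- order(classes)
  out <- t(apply(prob, 1, function(p) classes[ordc][order(-p[ordc])]))
  dimnames(out) <- NULL
  out
}

#' Predict ranked class codes
#'
#' @param model A [train_grf_model()] fit.
#' @param X Feature matrix with (at least) the model's features.
#' @return Matrix of class codes, one row per input row, columns in
#'   decreasing predicted probability (rank 1 first).
#' @export
predict_ranked <- function(model, X) {
  stopifnot(inherits(model, "grf_model"))
  X <- as.matrix(X)
  missing_feats <- setdiff(model$features, colnames(X))
  if (length(missing_feats)) {
    rlang::abort(sprintf("missing feature(s): %s",
                         paste(utils::head(missing_feats, 3), collapse = ", ")))
  }
  prob <- predict(model$forest, X[, model$features, drop = FALSE],
                  type = "prob")
  rank_probabilities(prob, model$classes)
}

#' Retrain on a projected label axis
#'
#' Re-fits the classifier for speed-only or incline-only prediction using
#' the same selected features and the same train/test partition as the
#' combined-task model (features are deliberately not reselected).
#'
#' @param X Full feature matrix (all rows) restricted to any superset of
#'   `features`.
#' @param conditions Data frame of `speed_mps`/`incline_deg`, one row per
#'   row of `X`.
#' @param is_train Logical training mask from [split_train_test()].
#' @param features Selected feature names from the combined task.
#' @param axis `"speed"` or `"incline"`.
#' @param n_trees,seed Forest parameters.
#' @return A list with the fitted `model`, the axis `labels`, test-set
#'   `rankings` and a one-row `metrics` tibble (top-1 accuracy, weighted
#'   precision/recall, class count).
#' @export
retrain_axis <- function(X, conditions, is_train, features,
                         axis = c("speed", "incline"), n_trees = 100,
                         seed = 1) {
  axis <- match.arg(axis)
  X <- as.matrix(X)
  y <- project_labels(conditions, axis)
  classes <- sort(unique(y))
  model <- train_grf_model(X[is_train, features, drop = FALSE], y[is_train],
                           classes = classes, n_trees = n_trees, seed = seed)
  rankings <- predict_ranked(model, X[!is_train, , drop = FALSE])
  truth <- y[!is_train]
  pr <- weighted_precision_recall(truth, rankings[, 1])
  metrics <- tibble::tibble(task = paste0(axis, "_", length(classes)),
                            n_classes = length(classes),
                            top1 = topk_accuracy(truth, rankings, 1),
                            precision_w = pr$precision_w,
                            recall_w = pr$recall_w)
  list(model = model, labels = y, rankings = rankings, metrics = metrics)
}
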