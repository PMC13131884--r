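# Two-stage feature selection on training data only:
#  1. correlated-group pruning — greedy grouping at |Pearson r| > threshold,
#     keeping the member whose single-feature decision tree scores best
#     under stratified cross-validation;
#  2. top-K ranking by one-way ANOVA F-score, with K chosen by the
#     one-standard-error rule over stratified 5-fold cross-validation of
#     the downstream classifier.

#' Stratified fold assignment
#'
#' Assigns each row to one of `k` folds, stratified by class so every fold
#' sees (near-)proportional class composition. Classes with fewer rows than
#' folds appear in a subset of folds. Uses the current RNG state; seed the
#' RNG for reproducibility.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Group features by pairwise correlation
#'
#' Greedy grouping in column order: each feature joins the first existing
#' group containing at least one member with `|Pearson r| > threshold`,
#' otherwise it founds a new group.
#'
#' @param X Numeric matrix (or data frame) of training features, with
#'   column names.
#' @param threshold Absolute correlation threshold (default 0.8).
#' @return A list of character vectors of feature names (the groups, in
#'   founding order).
#' @export
correlated_groups <- function(X, threshold = 0.8) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, !is.null(colnames(X)))
  C <- abs(suppressWarnings(stats::cor(X)))
  C[!is.finite(C)] <- 0
  p <- ncol(X)
  groups <- list()
  for (i in seq_len(p)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (any(C[i, groups[[g]]] > threshold)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- i
  }
  lapply(groups, function(g) colnames(X)[g])
}

#' Pick the best-performing feature of a correlated group
#'
#' Scores each member by the stratified cross-validated accuracy of a
#' depth-limited single-feature decision tree and retains the highest
#' scorer (ties broken toward the lexicographically first name); all other
#' members of the group are removed from consideration.
#'
#' @param X Training feature matrix with column names.
#' @param y Training class labels.
#' @param group Character vector of member feature names.
#' @param folds Number of CV folds (default 3); reduced with a warning if
#'   the rarest class has fewer rows.
#' @return The retained feature name.
#' @export
best_in_group <- function(X, y, group, folds = 3) {
  stopifnot(length(group) >= 1)
  if (length(group) == 1) return(group)
  y <- factor(y)
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(sprintf("reducing single-feature CV folds from %d to %d (rarest class has %d rows)",
                 folds, max(2L, min_class), min_class))
    folds <- max(2L, min_class)
  }
  fold <- stratified_folds(y, folds)
  acc <- vapply(group, function(f) {
    x <- X[, f]
    hits <- 0L
    for (k in seq_len(folds)) {
      tr <- fold != k
      df_tr <- data.frame(y = y[tr], x = x[tr])
      fit <- rpart::rpart(y ~ x, data = df_tr, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = 5, cp = 0, minsplit = 5,
                            minbucket = 2, xval = 0))
      pred <- predict(fit, newdata = data.frame(x = x[!tr]), type = "class")
      hits <- hits + sum(pred == y[!tr])
    }
    hits / length(y)
  }, numeric(1))
  cands <- group[acc == max(acc)]
  sort(cands)[1]
}

#' Per-feature one-way ANOVA F statistics
#'
#' For each column, the classical one-way F ratio of between-class to
#' within-class variance: `F = (SSB / (k - 1)) / (SSW / (n - k))`. Columns
#' with zero within-class variance but nonzero between-class variance get
#' `+Inf` (perfectly separating features rank first).
#'
#' @param X Numeric matrix (or data frame) of features.
#' @param y Class labels; at least two classes, each with at least two rows.
#' @return Named numeric vector of F statistics.
#' @export
anova_f_scores <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- unique(y)
  if (length(classes) < 2) rlang::abort("ANOVA F needs at least two classes")
  n <- nrow(X)
  k <- length(classes)
  grand <- colMeans(X)
  tot_ss <- colSums(X^2) - n * grand^2
  ssb <- numeric(ncol(X))
  for (cl in classes) {
    idx <- y == cl
    nc <- sum(idx)
    mc <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + nc * (mc - grand)^2
  }
  ssw <- pmax(tot_ss - ssb, 0)
  eps <- 1e-12 * pmax(tot_ss, 1)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  f[ssw <= eps & ssb > eps] <- Inf
  f[ssw <= eps & ssb <= eps] <- 0
  names(f) <- colnames(X)
  f
}

#' The one-standard-error choice on a cross-validation curve
#'
#' Given mean CV accuracy and its standard error per candidate K, returns
#' the smallest K whose mean is within one standard error (of the best K)
#' below the best mean.
#'
#' @param k_grid Candidate K values, ascending.
#' @param cv_mean,cv_se Mean and standard error of CV accuracy per K.
#' @return The chosen K.
#' @export
one_se_choice <- function(k_grid, cv_mean, cv_se) {
  stopifnot(length(k_grid) == length(cv_mean), length(cv_mean) == length(cv_se),
            !is.unsorted(k_grid))
  best <- which.max(cv_mean)
  bound <- cv_mean[best] - cv_se[best]
  k_grid[which(cv_mean >= bound)[1]]
}

#' Choose the number of features by the one-standard-error rule
#'
#' For each candidate K, trains the downstream Random Forest on the top-K
#' features by F-score under stratified cross-validation and records the
#' mean fold accuracy and its standard error (`SD(fold accuracies) /
#' sqrt(folds)`). The chosen K is the smallest one whose mean accuracy is
#' within one standard error of the best mean (least complex model not
#' meaningfully worse than the best).
#'
#' @param X Training feature matrix with column names.
#' @param y Training class labels.
#' @param k_grid Candidate K values, ascending; values exceeding the
#'   number of available features are clamped with a warning.
#' @param folds CV folds (default 5).
#' @param seed Integer seed for fold assignment and forest fitting.
#' @param f_scores Optional precomputed [anova_f_scores()].
#' @param n_trees Trees per forest (default 100).
#' @return A list with `k_grid`, `cv_mean`, `cv_se`, `chosen_k`, `ranking`
#'   (features in decreasing F-score order).
#' @export
choose_k_one_se <- function(X, y, k_grid = c(5, 10, 15, 20, 30, 40, 50, 75, 100),
                            folds = 5, seed = 1, f_scores = NULL,
                            n_trees = 100) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(f_scores)) f_scores <- anova_f_scores(X, y)
  # rank by F descending; ties broken by name for determinism
  ord <- order(-f_scores, names(f_scores))
  ranking <- names(f_scores)[ord]
  p <- length(ranking)
  if (any(k_grid > p)) {
    warn(sprintf("k values above %d available features were clamped", p))
    k_grid <- sort(unique(pmin(k_grid, p)))
  }
  withr::with_seed(as.integer(seed) %% 2147483647L, {
    fold <- stratified_folds(y, folds)
    cv <- vapply(k_grid, function(k) {
      feats <- ranking[seq_len(k)]
      accs <- vapply(seq_len(folds), function(fk) {
        tr <- fold != fk
        fit <- randomForest::randomForest(
          x = X[tr, feats, drop = FALSE], y = y[tr], ntree = n_trees)
        mean(predict(fit, X[!tr, feats, drop = FALSE]) == y[!tr])
      }, numeric(1))
      c(mean(accs), stats::sd(accs) / sqrt(folds))
    }, numeric(2))
  })
  cv_mean <- cv[1, ]
  cv_se <- cv[2, ]
  list(k_grid = k_grid, cv_mean = cv_mean, cv_se = cv_se,
       chosen_k = one_se_choice(k_grid, cv_mean, cv_se), ranking = ranking)
}

#' Run the full two-stage feature selection
#'
#' Correlated-group pruning, then top-K F-score ranking with the
#' one-standard-error K choice, on training rows only.
#'
#' @param X_train Numeric training feature matrix (or tibble of numeric
#'   columns) with feature names.
#' @param y_train Training class labels.
#' @param cor_threshold Absolute correlation threshold for grouping
#'   (default 0.8).
#' @param k_grid Candidate K values.
#' @param folds Folds for the K-choice CV (default 5).
#' @param tree_folds Folds for the single-feature tree CV (default 3).
#' @param seed Integer seed governing all CV randomness.
#' @param n_trees Trees per forest in the K-choice CV.
#' @return An object of class `selection_result`: list with
#'   `removed_correlated`, `kept_after_correlation`, `f_scores`, `k_grid`,
#'   `cv_mean`, `cv_se`, `chosen_k`, `selected`, `seed`.
#' @export
select_features <- function(X_train, y_train, cor_threshold = 0.8,
                            k_grid = c(5, 10, 15, 20, 30, 40, 50, 75, 100),
                            folds = 5, tree_folds = 3, seed = 1,
                            n_trees = 100) {
  X <- as.matrix(X_train)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(y_train))
  seed <- as.integer(seed) %% 2147483647L
  groups <- correlated_groups(X, cor_threshold)
  kept <- withr::with_seed(seed, {
    vapply(groups, function(g) best_in_group(X, y_train, g, folds = tree_folds),
           character(1))
  })
  removed <- setdiff(colnames(X), kept)
  Xk <- X[, kept, drop = FALSE]
  f <- anova_f_scores(Xk, y_train)
  ck <- choose_k_one_se(Xk, y_train, k_grid = k_grid, folds = folds,
                        seed = seed + 1L, f_scores = f, n_trees = n_trees)
  structure(list(removed_correlated = removed,
                 kept_after_correlation = kept,
                 f_scores = f,
                 k_grid = ck$k_grid, cv_mean = ck$cv_mean, cv_se = ck$cv_se,
                 chosen_k = ck$chosen_k,
                 selected = ck$ranking[seq_len(ck$chosen_k)],
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features in -> %d after correlation pruning -> %d selected (K by 1-SE rule)\n",
              length(x$removed_correlated) + length(x$kept_after_correlation),
              length(x$kept_after_correlation), x$chosen_k))
  invisible(x)
}

#' Serialize a selection result to JSON for audit
#'
#' Writes the full selection audit trail (features removed at the
#' correlation stage, per-feature F-scores, the CV curve and the chosen K)
#' as a JSON file.
#'
#' @param x A `selection_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(x, path) {
  stopifnot(inherits(x, "selection_result"))
  payload <- list(
    removed_correlated = x$removed_correlated,
    kept_after_correlation = x$kept_after_correlation,
    f_scores = as.list(x$f_scores),
    k_grid = x$k_grid, cv_mean = x$cv_mean, cv_se = x$cv_se,
    chosen_k = x$chosen_k, selected = x$selected, seed = x$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Tidy a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A tibble with one row per feature surviving correlation pruning:
#'   `feature`, `f_score`, `rank`, `selected`.
#' @export
tidy.selection_result <- function(x, ...) {
  ord <- order(-x$f_scores, names(x$f_scores))
  tibble::tibble(feature = names(x$f_scores)[ord],
                 f_score = unname(x$f_scores[ord]),
                 rank = seq_along(ord),
                 selected = names(x$f_scores)[ord] %in% x$selected)
}

#' One-row summary of a selection result
#'
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return A one-row tibble: feature counts at each stage, the chosen K,
#'   and the CV accuracy at the chosen and best K.
#' @export
glance.selection_result <- function(x, ...) {
  best <- which.max(x$cv_mean)
  chosen <- match(x$chosen_k, x$k_grid)
  tibble::tibble(
    n_features_in = length(x$removed_correlated) + length(x$kept_after_correlation),
    n_after_correlation = length(x$kept_after_correlation),
    chosen_k = x$chosen_k,
    best_k = x$k_grid[best],
    cv_accuracy_chosen = x$cv_mean[chosen],
    cv_accuracy_best = x$cv_mean[best],
    cv_se_best = x$cv_se[best])
}
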