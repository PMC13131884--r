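test_that("stratified split yields per-class 80/20 with train coverage", {
  labels <- rep(0:17, each = 10)
  is_train <- split_train_test(labels, 0.2, seed = 5)
  expect_equal(sum(is_train), 144)
  expect_equal(sum(!is_train), 36)
  per_class <- table(labels[!is_train])
  expect_true(all(per_class == 2))
  expect_setequal(unique(labels[is_train]), 0:17)
  # same seed, same mask; zero fraction keeps everything in train
  expect_identical(is_train, split_train_test(labels, 0.2, seed = 5))
  expect_true(all(split_train_test(labels, 0, seed = 1)))
  expect_warning(split_train_test(c(1, 1, 2), 0.2, seed = 1), "single row")
})

test_that("label projection reduces the grid to its axes", {
  grid <- condition_grid()
  expect_equal(project_labels(data.frame(speed_mps = 0.8, incline_deg = 15),
                              "speed"), 0.8)
  expect_equal(sort(unique(project_labels(grid, "speed"))),
               c(0.8, 1.2, 1.6))
  expect_equal(sort(unique(project_labels(grid, "incline"))),
               c(0, 5, 10, 15, 20, 25))
})

test_that("the forest separates a separable toy problem deterministically", {
  withr::with_seed(8, {
    y <- rep(0:1, each = 30)
    X <- cbind(f1 = y * 10 + rnorm(60, sd = 0.2), f2 = rnorm(60))
  })
  tr <- rep(c(TRUE, FALSE), 30)
  m <- train_grf_model(X[tr, ], y[tr], n_trees = 50, seed = 3)
  r <- predict_ranked(m, X[!tr, ])
  expect_equal(topk_accuracy(y[!tr], r, 1), 1.0)
  m2 <- train_grf_model(X[tr, ], y[tr], n_trees = 50, seed = 3)
  expect_identical(predict_ranked(m2, X[!tr, ]), r)
  expect_error(train_grf_model(X, rep(1, 60)), "two classes")
  expect_error(predict_ranked(m, X[, "f2", drop = FALSE]), "missing feature")
})

test_that("pure-noise features yield near-chance accuracy", {
  accs <- sapply(1:10, function(s) {
    withr::with_seed(300 + s, {
      y <- rep(0:3, each = 100)
      X <- matrix(rnorm(400 * 5), 400, 5,
                  dimnames = list(NULL, paste0("n", 1:5)))
    })
    tr <- split_train_test(y, 0.2, seed = s)
    m <- train_grf_model(X[tr, ], y[tr], n_trees = 100, seed = s)
    topk_accuracy(y[!tr], predict_ranked(m, X[!tr, ]), 1)
  })
  expect_equal(mean(accs), 0.25, tolerance = 0.3)
  expect_lt(mean(accs), 0.35)
  expect_gt(mean(accs), 0.15)
})

test_that("probability rankings are deterministic with code-ordered ties", {
  prob <- rbind(c(0.5, 0.3, 0.2), c(1, 1, 1) / 3, c(0.2, 0.3, 0.5))
  r <- rank_probabilities(prob, classes = 0:2)
  expect_equal(r[1, ], c(0, 1, 2))
  expect_equal(r[2, ], c(0, 1, 2))   # uniform: ascending class codes
  expect_equal(r[3, ], c(2, 1, 0))
  # rank-1 equals argmax on fitted-forest probabilities
  withr::with_seed(2, {
    y <- rep(0:2, each = 20)
    X <- cbind(a = y + rnorm(60, sd = 0.4), b = rnorm(60))
  })
  m <- train_grf_model(X, y, n_trees = 50, seed = 1)
  prob_m <- predict(m$forest, X, type = "prob")
  r_m <- predict_ranked(m, X)
  expect_equal(r_m[, 1], unname(m$classes[apply(prob_m, 1, which.max)]))
})

test_that("axis retraining keeps features and partition fixed", {
  sess <- simulate_session(gait_params(), condition_grid(c(0, 25),
                                                         c(0.8, 1.6)),
                           collect_s = 12, seed = 44)
  steps <- segment_session(sess$recordings)
  padded <- pad_steps(steps)
  is_train <- split_train_test(paste(steps$speed_mps, steps$incline_deg),
                               0.2, seed = 1)
  scaled <- apply_minmax(fit_minmax(padded, is_train), padded)
  feats <- drop_invalid_features(extract_features(scaled), rows = is_train)
  X <- as.matrix(feats[setdiff(names(feats), "step_id")])
  conditions <- steps[, c("speed_mps", "incline_deg")]
  selected <- colnames(X)[1:10]
  ax <- retrain_axis(X, conditions, is_train, selected, axis = "speed",
                     n_trees = 50, seed = 2)
  expect_identical(ax$model$features, selected)
  expect_equal(ax$metrics$n_classes, 2)
  expect_equal(nrow(ax$rankings), sum(!is_train))
})

test_that("correct combined predictions project to correct axis predictions", {
  grid <- condition_grid()
  enc <- condition_encoder(grid)
  codes <- encode_conditions(grid, enc)
  # a perfect combined prediction determines both axis labels exactly
  pred <- codes
  dec <- decode_conditions(pred, enc)
  expect_identical(project_labels(dec, "speed"), grid$speed_mps)
  expect_identical(project_labels(dec, "incline"), grid$incline_deg)
})
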