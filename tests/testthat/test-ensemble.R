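test_that("weighted error sums misclassified weight exactly", {
  expect_equal(weighted_error(c(1, 1, -1, -1), c(1, 1, -1, -1), rep(0.25, 4)), 0)
  expect_equal(weighted_error(c(1, 1, 1, -1), c(1, 1, -1, -1), rep(0.25, 4)), 0.25)
  expect_equal(weighted_error(c(-1, 1, -1, -1), c(1, 1, -1, -1),
                              c(0.7, 0.1, 0.1, 0.1)), 0.7)
  expect_error(weighted_error(c(1, -1), c(1, -1), c(0.6, 0.6)), "sum to 1")
})

test_that("learner weight is the half-log-odds of the error", {
  expect_equal(learner_weight(0.5), 0)
  expect_equal(learner_weight(0.1), 0.5 * log(9))
  expect_equal(learner_weight(0.9), -learner_weight(0.1))
  expect_true(is.finite(learner_weight(0)))
  expect_true(is.finite(learner_weight(1)))
})

test_that("AdaBoost separates 1-D data in one round and beats the single-stump ceiling", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m1 <- adaboost_train(x, y, rounds = 1)
  expect_equal(predict(m1, x, type = "label"), y)

  # additive signal spread over three features: no single stump can use
  # more than one of them, boosting combines all three
  d <- generate_feature_dataset(
    synth_feature_config(n_samples = 200, n_features = 6, n_informative = 3,
                         effect_size = 2, seed = 21))
  ceiling_acc <- oracle_best_stump_accuracy(d$X, ifelse(d$y == 1, 1, -1))
  m <- adaboost_train(d$X, d$y, rounds = 20)
  expect_gt(mean(predict(m, d$X, type = "label") == d$y), ceiling_acc)

  expect_error(adaboost_train(x, rep(1, 6)), "single class")
})

test_that("Gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini_impurity(1), 0)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_equal(gini_impurity(c(0.7, 0.3)), 0.42)
  expect_error(gini_impurity(c(0.7, 0.7)), "sum to 1")
})

test_that("decision tree splits greedily and handles degenerate input", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  tree <- dt_train(x, y)
  expect_equal(predict(tree, x, type = "label"), y)
  expect_true(tree$root$left$leaf && tree$root$right$leaf)  # depth 1 suffices

  pure <- dt_train(matrix(rnorm(10), ncol = 2), rep(1, 5))
  expect_true(pure$root$leaf)
  expect_equal(pure$root$prop1, 1)

  dup <- dt_train(matrix(1, 6, 2), c(0, 0, 1, 1, 0, 1))
  expect_true(dup$root$leaf)
  expect_equal(dup$root$prop1, 0.5)
})

test_that("the root split matches an exhaustive impurity-decrease search", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:12, 1)
    X <- matrix(sample(1:5, n * 3, replace = TRUE) + runif(n * 3) * 0.01, n, 3)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    tree <- dt_train(X, y, max_depth = 1)
    want <- oracle_best_first_split(X, y)
    if (tree$root$leaf) {
      expect_lte(want, 1e-10)
    } else {
      left <- X[, tree$root$feature] <= tree$root$threshold
      g <- function(yy) if (length(yy)) 1 - mean(yy)^2 - (1 - mean(yy))^2 else 0
      got <- g(y) - (sum(left) * g(y[left]) + sum(!left) * g(y[!left])) / n
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("random forest learns planted signal and is seed-reproducible", {
  d <- generate_feature_dataset(synth_feature_config(400, 40, 5, 3, seed = 4))
  tr <- rep(c(TRUE, FALSE), length.out = 400)
  rf <- rf_train(d$X[tr, ], d$y[tr], R = 50, seed = 7)
  acc <- mean(predict(rf, d$X[!tr, ], type = "label") == d$y[!tr])
  expect_gte(acc, 0.9)

  rf2 <- rf_train(d$X[tr, ], d$y[tr], R = 50, seed = 7)
  expect_identical(predict(rf, d$X[!tr, ]), predict(rf2, d$X[!tr, ]))

  expect_error(rf_train(d$X, d$y, R = 5, h = 40), "smaller than")

  # no bootstrap, h = D - 1: a single randomized tree at least matches a
  # depth-capped baseline on its training data
  r1 <- rf_train(d$X[tr, ], d$y[tr], R = 1, h = 39, seed = 1, bootstrap = FALSE)
  base <- dt_train(d$X[tr, ], d$y[tr], max_depth = 3)
  acc_r1 <- mean(predict(r1, d$X[tr, ], type = "label") == d$y[tr])
  acc_base <- mean(predict(base, d$X[tr, ], type = "label") == d$y[tr])
  expect_gte(acc_r1, acc_base)
})

test_that("fusion is an exact convex combination of base scores", {
  leaf_model <- function(p) structure(list(root = list(leaf = TRUE, prop1 = p)),
                                      class = "dt_model")
  X <- matrix(0, 4, 2)
  em <- ensemble_model(leaf_model(0.9), leaf_model(0.2), leaf_model(0.6),
                       weights = c(0.5, 0.3, 0.2))
  out <- fuse_predict(em, X)
  expect_equal(out$scores, rep(0.63, 4))
  expect_equal(out$labels, rep(1L, 4))

  em1 <- ensemble_model(leaf_model(0.9), leaf_model(0.2), leaf_model(0.6),
                        weights = c(1, 0, 0))
  expect_equal(fuse_predict(em1, X)$scores, rep(0.9, 4))

  em3 <- ensemble_model(leaf_model(0.9), leaf_model(0.2), leaf_model(0.6))
  expect_equal(fuse_predict(em3, X)$scores,
               rep(mean(c(0.9, 0.2, 0.6)), 4))

  expect_error(ensemble_model(leaf_model(0.9), leaf_model(0.2),
                              leaf_model(0.6), weights = c(0.9, 0.3, 0.2)),
               "simplex")

  # convexity on real trained models
  d <- generate_feature_dataset(synth_feature_config(120, 6, 2, 2, seed = 6))
  ab <- adaboost_train(d$X, d$y, rounds = 5)
  rf <- rf_train(d$X, d$y, R = 10, seed = 2)
  dt <- dt_train(d$X, d$y, max_depth = 4)
  set.seed(12)
  for (i in 1:10) {
    w <- project_simplex(runif(3))
    out <- fuse_predict(ensemble_model(ab, rf, dt, w), d$X)
    expect_true(all(out$scores >= apply(out$base, 1, min) - 1e-12))
    expect_true(all(out$scores <= apply(out$base, 1, max) + 1e-12))
  }
})

test_that("ensemble archives round-trip and validate on load", {
  d <- generate_feature_dataset(synth_feature_config(60, 4, 2, 2, seed = 8))
  em <- ensemble_model(adaboost_train(d$X, d$y, rounds = 3),
                       rf_train(d$X, d$y, R = 5, seed = 3),
                       dt_train(d$X, d$y), weights = c(0.2, 0.5, 0.3))
  path <- withr::local_tempfile(fileext = ".rds")
  save_ensemble(em, path)
  back <- load_ensemble(path)
  expect_equal(fuse_predict(back, d$X)$scores, fuse_predict(em, d$X)$scores)

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "something-else"), bad)
  expect_error(load_ensemble(bad), "archive")
})
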