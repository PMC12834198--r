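roster <- default_roster()

test_that("models are configured with the roster hyperparameters", {
  m1 <- build_model(roster[1, ])
  expect_equal(m1$profile$hyperparameters$n_estimators, 130L)
  expect_equal(m1$profile$hyperparameters$max_depth, 15L)
  expect_equal(m1$profile$hyperparameters$max_features, 0.75)
  m2 <- build_model(roster[2, ])
  expect_equal(m2$profile$hyperparameters$n_neighbors, 5L)
  m3 <- build_model(roster[3, ])
  expect_equal(m3$profile$hyperparameters$learning_rate, 0.01)
  expect_equal(m3$profile$hyperparameters$n_estimators, 180L)
  bad <- roster[1, ]
  bad$model_kind <- "mlp"
  expect_error(build_model(bad), "unknown model_kind")
})

test_that("every model family emits probability-simplex rows", {
  cohort <- tiny_cohort(n = 240)
  X <- as.matrix(cohort[cohort_feature_names()])
  y <- cohort$outcome
  for (i in seq_len(nrow(roster))) {
    m <- build_model(roster[i, ])
    m <- train_local(m, X[1:180, ], y[1:180], seed = 5)
    probs <- predict_soft(m, X[181:240, ])
    expect_equal(dim(probs), c(60, 2))
    expect_true(all(probs >= 0), info = roster$model_kind[i])
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-9)
    # validation accuracy must beat chance on separable data
    acc <- evaluate_predictions(probs, y[181:240])$accuracy
    expect_gt(acc, 0.5)
  }
})

test_that("training is deterministic and pseudo-append matters only via data", {
  cohort <- tiny_cohort(n = 240)
  X <- as.matrix(cohort[cohort_feature_names()])
  y <- cohort$outcome
  for (kind_row in c(1, 3)) {  # the stochastic learners
    m <- build_model(roster[kind_row, ])
    f1 <- train_local(m, X[1:150, ], y[1:150], seed = 7)
    f2 <- train_local(m, X[1:150, ], y[1:150], seed = 7)
    expect_identical(predict_soft(f1, X[151:170, ]),
                     predict_soft(f2, X[151:170, ]))
    # empty pseudo-set is a no-op append
    f3 <- train_local(m, X[1:150, ], y[1:150],
                      pseudo_features = X[0, , drop = FALSE],
                      pseudo_labels = integer(0), seed = 7)
    expect_identical(predict_soft(f1, X[151:170, ]),
                     predict_soft(f3, X[151:170, ]))
    # appending pseudo rows equals training on the concatenated data
    f4 <- train_local(m, X[1:150, ], y[1:150],
                      pseudo_features = X[151:160, ], pseudo_labels = y[151:160],
                      seed = 7)
    f5 <- train_local(m, X[1:160, ], y[1:160], seed = 7)
    expect_equal(predict_soft(f4, X[161:170, ]),
                 predict_soft(f5, X[161:170, ]), tolerance = 1e-12)
  }
})

test_that("single-class shards raise an explicit training error", {
  cohort <- tiny_cohort(n = 100)
  X <- as.matrix(cohort[cohort_feature_names()])
  m <- build_model(roster[1, ])
  expect_error(train_local(m, X[1:30, ], rep(1L, 30), seed = 1),
               "single class")
  expect_error(predict_soft(m, X), "not been fitted")
})

test_that("nearest-neighbour scoring memorizes training points at k = 1", {
  prof <- roster[2, ]
  prof$hyperparameters <- list(list(n_neighbors = 1L))
  m <- build_model(prof)
  X <- matrix(c(0, 0, 1, 1, 0, 1, 5, 5), ncol = 2, byrow = TRUE)
  y <- c(0L, 0L, 1L, 1L)
  m <- train_local(m, X, y, seed = 1)
  probs <- predict_soft(m, X)
  expect_equal(probs[, "1"], as.numeric(y))
})

test_that("a depth-1 tree reports empirical leaf class fractions", {
  prof <- roster[4, ]
  prof$hyperparameters <- list(list(criterion = "gini", max_depth = 1))
  m <- build_model(prof)
  set.seed(8)
  x1 <- c(runif(60, -3, -1), runif(60, 1, 3))  # clean gap so the split sits at 0
  X <- cbind(x1, rnorm(120))
  y <- as.integer(c(rbinom(60, 1, 0.1), rbinom(60, 1, 0.9)))
  m <- train_local(m, X, y, seed = 8)
  probs <- predict_soft(m, X)
  # leaf-count oracle: rows landing in the same side share the leaf fraction
  left <- X[, 1] < 0
  expect_equal(unname(probs[left, "1"][1]), mean(y[left]), tolerance = 1e-9)
  expect_equal(unname(probs[!left, "1"][1]), mean(y[!left]), tolerance = 1e-9)
})

test_that("metrics match hand-computed confusion arithmetic", {
  perfect <- evaluate_predictions(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))

  # TP=8 FP=2 FN=2 TN=8
  truth <- c(rep(1L, 10), rep(0L, 10))
  pred <- c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8))
  m <- evaluate_predictions(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_false(m$flagged)

  allneg <- evaluate_predictions(rep(0L, 20), truth)
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$precision, 0)
  expect_true(allneg$flagged)

  expect_error(evaluate_predictions(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("f1 is the harmonic mean of reported precision and recall", {
  set.seed(10)
  for (i in 1:20) {
    truth <- rbinom(50, 1, 0.4)
    pred <- rbinom(50, 1, 0.5)
    m <- evaluate_predictions(pred, truth)
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
    if (m$precision > 0 && m$recall > 0) {
      expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall),
                   tolerance = 1e-12)
    }
  }
})
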