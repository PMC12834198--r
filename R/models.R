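#' Build an untrained local model from a participant profile
#'
#' Configures one of the five supported model families with the
#' hyperparameters recorded in the participant's roster row:
#' random forest (130 trees, depth 15, 75% feature sampling), k-nearest
#' neighbours (k = 5), gradient boosted trees (learning rate 0.01,
#' depth 10, 180 rounds), decision tree (Gini, unbounded depth) and
#' linear SVM (C = 1) with logistic squashing of the signed margin for
#' probability output.
#'
#' @param profile One roster row (a one-row tibble or a named list with
#'   `id`, `model_kind`, `hyperparameters`).
#' @return An object of class `local_model` (unfitted).
#' @examples
#' m <- build_model(default_roster()[1, ])
#' m$profile$model_kind
#' @export
build_model <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1)
    profile <- list(
      id = profile$id, name = profile$name,
      model_kind = profile$model_kind,
      hyperparameters = profile$hyperparameters[[1]],
      static_weight = profile$static_weight
    )
  }
  known <- c(
    "random_forest", "knn", "gradient_boosted_trees",
    "decision_tree", "linear_svm"
  )
  if (!profile$model_kind %in% known) {
    stop(
      "unknown model_kind '", profile$model_kind, "'; supported kinds: ",
      paste(known, collapse = ", ")
    )
  }
  structure(
    list(
      profile = profile,
      fitted = NULL,
      last_validation_accuracy = NA_real_
    ),
    class = "local_model"
  )
}

#' Train a local model on its shard plus current pseudo-labels
#'
#' Fits the model on the row-concatenation of the participant's private
#' shard and the current round's accepted pseudo-labelled pool (possibly
#' empty). Training is deterministic under a fixed seed for every model
#' family.
#'
#' @param model A `local_model`.
#' @param shard_features,shard_labels The private training shard.
#' @param pseudo_features,pseudo_labels Accepted pseudo-labelled records
#'   (may be `NULL` / empty).
#' @param seed Integer seed.
#' @return The fitted `local_model`.
#' @export
train_local <- function(model, shard_features, shard_labels,
                        pseudo_features = NULL, pseudo_labels = NULL,
                        seed = 1L) {
  stopifnot(inherits(model, "local_model"))
  x <- as.matrix(shard_features)
  y <- as.integer(shard_labels)
  if (!is.null(pseudo_features) && NROW(pseudo_features) > 0) {
    x <- rbind(x, as.matrix(pseudo_features))
    y <- c(y, as.integer(pseudo_labels))
  }
  if (nrow(x) == 0) stop("training shard is empty")
  if (length(unique(y)) < 2) {
    stop(
      "participant ", model$profile$id,
      ": training labels contain a single class; cannot fit a binary classifier"
    )
  }
  hp <- model$profile$hyperparameters
  p <- ncol(x)

  fitted <- with_preserved_seed(seed, switch(
    model$profile$model_kind,
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0L, 1L)),
      num.trees = hp$n_estimators,
      max.depth = hp$max_depth,
      mtry = max(1L, floor(hp$max_features * p)),
      probability = TRUE,
      num.threads = 1L,
      seed = as.integer(seed)
    ),
    knn = list(x = x, y = y, k = hp$n_neighbors),
    gradient_boosted_trees = xgboost::xgboost(
      x = x, y = factor(y, levels = c(0L, 1L)),
      objective = "binary:logistic",
      nrounds = hp$n_estimators,
      learning_rate = hp$learning_rate,
      max_depth = hp$max_depth,
      nthreads = 1L,
      seed = as.integer(seed),
      verbosity = 0L
    ),
    decision_tree = {
      df <- data.frame(x, .y = factor(y, levels = c(0L, 1L)))
      rpart::rpart(
        .y ~ ., data = df, method = "class",
        parms = list(split = "gini"),
        control = rpart::rpart.control(
          cp = 0, minsplit = 2L, minbucket = 1L, xval = 0L,
          maxdepth = if (is.finite(hp$max_depth %||% Inf)) hp$max_depth else 30L
        )
      )
    },
    linear_svm = e1071::svm(
      x = x, y = factor(y, levels = c(0L, 1L)),
      kernel = "linear", cost = hp$cost, scale = FALSE
    )
  ))
  model$fitted <- fitted
  model$n_train <- nrow(x)
  model
}

#' Predict soft labels (class-probability rows)
#'
#' Returns an `n x 2` matrix with columns `"0"` and `"1"`; every row is a
#' probability distribution (non-negative, summing to 1). The linear SVM
#' has no native probabilities: its signed decision margin is squashed
#' through the logistic function, a monotone calibrated mapping.
#'
#' @param model A fitted `local_model`.
#' @param features Feature matrix to score.
#' @return Numeric matrix of class probabilities.
#' @export
predict_soft <- function(model, features) {
  stopifnot(inherits(model, "local_model"))
  if (is.null(model$fitted)) stop("model has not been fitted; call train_local() first")
  x <- as.matrix(features)
  probs <- switch(
    model$profile$model_kind,
    random_forest = {
      pr <- stats::predict(model$fitted, data = x, num.threads = 1L)$predictions
      pr[, c("0", "1"), drop = FALSE]
    },
    knn = knn_soft(model$fitted, x),
    gradient_boosted_trees = {
      p1 <- as.numeric(stats::predict(model$fitted, x, type = "response"))
      cbind("0" = 1 - p1, "1" = p1)
    },
    decision_tree = {
      pr <- stats::predict(model$fitted, newdata = data.frame(x), type = "prob")
      pr[, c("0", "1"), drop = FALSE]
    },
    linear_svm = {
      dv <- attr(
        stats::predict(model$fitted, newdata = x, decision.values = TRUE),
        "decision.values"
      )
      # e1071 orients the margin towards the first factor level named in
      # the column label ("a/b": positive margin favours class a).
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      margin_to_1 <- if (first == "1") dv[, 1] else -dv[, 1]
      p1 <- stats::plogis(margin_to_1)
      cbind("0" = 1 - p1, "1" = p1)
    }
  )
  probs <- as.matrix(probs)
  colnames(probs) <- c("0", "1")
  rownames(probs) <- NULL
  probs / rowSums(probs)
}

# Deterministic kNN class-probability scorer: the probability of class 1 is
# the class-1 fraction among the k nearest training rows (Euclidean); row
# order breaks distance ties, so replays are byte-stable.
knn_soft <- function(fit, x) {
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(x^2), rep(1, nrow(fit$x))) -
    2 * x %*% t(fit$x) +
    outer(rep(1, nrow(x)), rowSums(fit$x^2))
  p1 <- apply(d2, 1L, function(row) mean(fit$y[order(row)[seq_len(k)]]))
  cbind("0" = 1 - p1, "1" = p1)
}

#' Evaluate hard predictions against binary truth
#'
#' Standard binary-classification metrics with the diabetic class
#' (label 1) as positive. Zero-denominator precision or recall is
#' reported as 0 and flagged, so summary tables never contain `NaN`.
#'
#' @param predicted Predicted 0/1 labels (or a soft-label matrix, in
#'   which case the argmax is taken).
#' @param truth True 0/1 labels.
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`,
#'   `flagged` (TRUE when a zero denominator was substituted).
#' @examples
#' evaluate_predictions(c(1, 0, 1, 1), c(1, 0, 0, 1))
#' @export
evaluate_predictions <- function(predicted, truth) {
  if (is.matrix(predicted)) predicted <- max.col(predicted, ties.method = "first") - 1L
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length")
  }
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  flagged <- FALSE
  prec <- if (tp + fp == 0) {
    flagged <- TRUE
    0
  } else {
    tp / (tp + fp)
  }
  rec <- if (tp + fn == 0) {
    flagged <- TRUE
    0
  } else {
    tp / (tp + fn)
  }
  f1 <- if (prec + rec == 0) {
    flagged <- TRUE
    0
  } else {
    2 * prec * rec / (prec + rec)
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(truth),
    precision = prec,
    recall = rec,
    f1 = f1,
    flagged = flagged
  )
}

#' @export
print.local_model <- function(x, ...) {
  cat(
    "<local_model>", x$profile$model_kind,
    if (is.null(x$fitted)) "(unfitted)" else sprintf("(fitted, n=%d)", x$n_train),
    "\n"
  )
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
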