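# Learner fitting, prediction and inner-CV tuning for the classification
# protocol. Five families: AdaBoost (SAMME over rpart stumps), random forest,
# RBF support vector machine, k-nearest-neighbours (k = round(sqrt(n_train)),
# decremented if even), and a single-hidden-layer neural network.

fit_adaboost <- function(x, y, n_rounds = 60) {
  y <- droplevels(factor(y))
  K <- nlevels(y)
  n <- nrow(x)
  df <- data.frame(.y = y, x, check.names = TRUE)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, minsplit = 2, cp = -1, xval = 0,
                               maxcompete = 0, maxsurrogate = 0)
  for (m in seq_len(n_rounds)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
    pred <- stats::predict(stump, df, type = "class")
    miss <- pred != y
    err <- sum(w[miss]) / sum(w)
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 1 - 1 / K && m > 1) break
    alpha <- log((1 - err) / err) + log(K - 1)
    if (alpha <= 0 && m > 1) break
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, max(alpha, 1e-6))
    w <- w * exp(max(alpha, 1e-6) * miss)
    w <- w / sum(w)
    if (err < 1e-8) break      # perfect stump; further rounds add nothing
  }
  structure(list(stumps = stumps, alphas = alphas, levels = levels(y),
                 feat_names = colnames(df)[-1]),
            class = "pedmri_adaboost")
}

predict_adaboost <- function(model, x) {
  df <- data.frame(x, check.names = TRUE)
  colnames(df) <- model$feat_names[seq_len(ncol(df))]
  K <- length(model$levels)
  scores <- matrix(0, nrow(df), K, dimnames = list(NULL, model$levels))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], df, type = "class")
    scores[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      scores[cbind(seq_len(nrow(df)), as.integer(pred))] + model$alphas[m]
  }
  prob <- scores / pmax(rowSums(scores), 1e-12)
  cls <- factor(model$levels[max.col(scores, ties.method = "first")],
                levels = model$levels)
  list(class = cls, prob = prob)
}

# deterministic kNN: Euclidean distance, majority vote, ties broken by the
# smaller mean distance among tied classes, then by level order
knn_predict <- function(train_x, train_y, test_x, k) {
  train_y <- droplevels(factor(train_y))
  lev <- levels(train_y)
  k <- max(1L, min(as.integer(k), nrow(train_x)))
  prob <- matrix(0, nrow(test_x), length(lev), dimnames = list(NULL, lev))
  cls <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d2 <- colSums((t(train_x) - test_x[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(factor(train_y[nn], levels = lev))
    prob[i, ] <- as.numeric(votes) / k
    top <- which(votes == max(votes))
    if (length(top) > 1) {
      md <- vapply(names(votes)[top], function(cl)
        mean(d2[nn][train_y[nn] == cl]), numeric(1))
      top <- top[which.min(md)]
    }
    cls[i] <- names(votes)[top[1]]
  }
  list(class = factor(cls, levels = lev), prob = prob)
}

#' The root-n rule for the k-nearest-neighbours neighbourhood size
#'
#' k = round(sqrt(n_train)), decremented by one when even (tie avoidance),
#' never below 1.
#'
#' @param n_train Number of training rows.
#' @return Integer k.
#' @export
knn_k_rule <- function(n_train) {
  k <- max(1L, as.integer(round(sqrt(n_train))))
  if (k > 1L && k %% 2L == 0L) k <- k - 1L
  k
}

learner_grid <- function(classifier, p) {
  switch(classifier,
    adaboost = list(list(n_rounds = 40), list(n_rounds = 80)),
    random_forest = list(list(ntree = 300, mtry = max(1L, floor(sqrt(p)))),
                         list(ntree = 300, mtry = max(1L, floor(p / 3)))),
    svm = list(list(cost = 0.5), list(cost = 2), list(cost = 8)),
    knn = list(list()),
    neural_net = list(list(size = 3, decay = 0.1), list(size = 3, decay = 0.01),
                      list(size = 7, decay = 0.1), list(size = 7, decay = 0.01)),
    stop("unknown classifier: ", classifier))
}

fit_learner <- function(classifier, x, y, params = list()) {
  y <- droplevels(factor(y))
  x <- as.matrix(x)
  model <- switch(classifier,
    adaboost = fit_adaboost(x, y, params$n_rounds %||% 60),
    random_forest = randomForest::randomForest(
      x, y, ntree = params$ntree %||% 300,
      mtry = params$mtry %||% max(1L, floor(sqrt(ncol(x))))),
    svm = e1071::svm(x, y, kernel = "radial",
                     cost = params$cost %||% 1,
                     gamma = params$gamma %||% (1 / ncol(x)),
                     probability = TRUE),
    knn = list(train_x = x, train_y = y, k = knn_k_rule(nrow(x))),
    neural_net = {
      df <- data.frame(.y = y, x, check.names = TRUE)
      nnet::nnet(.y ~ ., data = df, size = params$size %||% 5,
                 decay = params$decay %||% 0.01, maxit = 300,
                 trace = FALSE, MaxNWts = 5000)
    })
  structure(list(classifier = classifier, model = model, levels = levels(y),
                 feat_names = colnames(x)),
            class = "pedmri_learner")
}

predict_learner <- function(fit, x) {
  x <- as.matrix(x)
  lev <- fit$levels
  out <- switch(fit$classifier,
    adaboost = predict_adaboost(fit$model, x),
    random_forest = {
      prob <- stats::predict(fit$model, x, type = "prob")
      list(class = factor(colnames(prob)[max.col(prob, ties.method = "first")],
                          levels = lev),
           prob = prob[, lev, drop = FALSE])
    },
    svm = {
      pr <- stats::predict(fit$model, x, probability = TRUE)
      prob <- attr(pr, "probabilities")[, lev, drop = FALSE]
      list(class = factor(as.character(pr), levels = lev), prob = prob)
    },
    knn = knn_predict(fit$model$train_x, fit$model$train_y, x, fit$model$k),
    neural_net = {
      raw <- stats::predict(fit$model, data.frame(x, check.names = TRUE),
                            type = "raw")
      prob <- if (length(lev) == 2L)
        cbind(1 - raw[, 1], raw[, 1]) else raw
      colnames(prob) <- lev
      list(class = factor(lev[max.col(prob, ties.method = "first")],
                          levels = lev),
           prob = prob)
    })
  out
}

# macro one-vs-rest AUC from a probability matrix
macro_ovr_auc <- function(prob, y) {
  y <- factor(y, levels = colnames(prob))
  aucs <- vapply(colnames(prob), function(cl) {
    lab <- factor(y == cl, levels = c(FALSE, TRUE))
    if (length(unique(lab)) < 2) return(NA_real_)
    roc_auc(prob[, cl], lab, positive = "TRUE")
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

# inner stratified 3-fold grid search maximising macro one-vs-rest AUC on the
# training data; budget caps the number of grid points evaluated
tune_learner <- function(classifier, x, y, budget = 6) {
  grid <- utils::head(learner_grid(classifier, ncol(x)), budget)
  if (length(grid) <= 1L) return(grid[[1]] %||% list())
  y <- droplevels(factor(y))
  if (any(table(y) < 3)) return(grid[[1]])
  folds <- stratified_kfold(y, k = 3)
  scores <- vapply(grid, function(params) {
    aucs <- vapply(1:3, function(f) {
      tr <- folds != f; te <- folds == f
      if (nlevels(droplevels(y[tr])) < nlevels(y)) return(NA_real_)
      fit <- fit_learner(classifier, x[tr, , drop = FALSE], y[tr], params)
      pr <- predict_learner(fit, x[te, , drop = FALSE])
      macro_ovr_auc(pr$prob, y[te])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  grid[[which.max(scores)]]
}

#' Oversample a minority class in a training set
#'
#' `replicate` duplicates minority rows; `smote` synthesises interpolated
#' points on segments between a minority row and one of its nearest minority
#' neighbours. With `amount = 1` (i.e. +100%) the minority count doubles.
#' Applied to training folds only — test folds are never touched.
#'
#' @param x Numeric feature matrix.
#' @param y Factor of class labels.
#' @param method `"none"`, `"replicate"` or `"smote"`.
#' @param target_class Class to oversample (default `"ependymoma"`).
#' @param amount Fractional increase of the target class (1 = +100%).
#' @param k_neighbours SMOTE neighbour count, truncated to minority size - 1.
#' @param seed Optional seed for the interpolation randomness.
#' @return List with augmented `x` and `y`.
#' @export
oversample <- function(x, y, method = c("none", "replicate", "smote"),
                       target_class = "ependymoma", amount = 1,
                       k_neighbours = 5, seed = NULL) {
  method <- match.arg(method)
  y <- factor(y)
  x <- as.matrix(x)
  if (method == "none") return(list(x = x, y = y))
  if (!target_class %in% levels(y))
    stop("target class '", target_class, "' not present in labels")
  idx <- which(y == target_class)
  n_new <- round(amount * length(idx))
  if (n_new == 0) return(list(x = x, y = y))
  run <- function() {
    if (method == "replicate") {
      take <- rep_len(idx, n_new)
      return(x[take, , drop = FALSE])
    }
    if (length(idx) < 2) stop("SMOTE requires at least 2 minority rows")
    k <- min(k_neighbours, length(idx) - 1)
    minority <- x[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(minority))
    new_rows <- matrix(NA_real_, n_new, ncol(x))
    for (j in seq_len(n_new)) {
      i <- ((j - 1) %% length(idx)) + 1
      nn <- order(d[i, ])[-1][seq_len(k)]
      nb <- nn[sample.int(k, 1)]
      u <- stats::runif(1)
      new_rows[j, ] <- minority[i, ] + u * (minority[nb, ] - minority[i, ])
    }
    new_rows
  }
  add <- if (is.null(seed)) run() else with_seed(seed, run())
  colnames(add) <- colnames(x)
  list(x = rbind(x, add),
       y = factor(c(as.character(y), rep(target_class, n_new)),
                  levels = levels(y)))
}
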