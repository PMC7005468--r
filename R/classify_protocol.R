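#' Configuration of one classification experiment
#'
#' @param task `"type"` (three tumour types) or `"grade"` (low/high).
#' @param feature_set `"all"`, `"roi"`, `"wb"`, or the shorthands
#'   `"univariate_roi"` / `"univariate_all"` (which also set
#'   `reduction = "univariate"`). ROI features include tumour volume.
#' @param reduction `"pca"` (95% variance, capped at N_min - 1 components),
#'   `"univariate"` (fold-wise univariate selection) or `"none"`.
#' @param classifier One of `adaboost`, `random_forest`, `svm`, `knn`,
#'   `neural_net`.
#' @param oversampling `"none"`, `"replicate"` or `"smote"` (+100% of the
#'   ependymoma training rows for the type task; of the minority grade for
#'   the grade task).
#' @param n_folds Outer stratified folds (default 3).
#' @param seed RNG seed for folds, oversampling and stochastic learners.
#' @param hyperopt_budget Maximum grid points evaluated by the inner tuner.
#' @param variance_target PCA cumulative-variance target (default 0.95).
#' @param cap_pre_oversampling If TRUE the PCA component cap N_min - 1 uses
#'   the pre-oversampling smallest group size.
#' @param select_alpha Base alpha of the fold-wise univariate screen.
#' @param max_selected Cap on selected features (default: all Bonferroni
#'   survivors, minimum 1).
#' @param features Explicit feature columns (overrides `feature_set`).
#' @param oversample_amount Fractional minority increase (default 1 = +100%).
#' @param smote_k SMOTE neighbour count.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(task = c("type", "grade"),
                              feature_set = "all",
                              reduction = c("pca", "univariate", "none"),
                              classifier = c("adaboost", "random_forest",
                                             "svm", "knn", "neural_net"),
                              oversampling = c("none", "replicate", "smote"),
                              n_folds = 3, seed = 1, hyperopt_budget = 6,
                              variance_target = 0.95,
                              cap_pre_oversampling = FALSE,
                              select_alpha = 0.05, max_selected = NULL,
                              features = NULL, oversample_amount = 1,
                              smote_k = 5) {
  task <- match.arg(task)
  if (feature_set %in% c("univariate_roi", "univariate_all")) {
    reduction <- "univariate"
    feature_set <- sub("univariate_", "", feature_set)
  } else {
    reduction <- match.arg(reduction)
  }
  if (!feature_set %in% c("all", "roi", "wb"))
    stop("feature_set must be all/roi/wb (or univariate_roi/univariate_all)")
  classifier <- match.arg(classifier)
  oversampling <- match.arg(oversampling)
  if (n_folds < 2) stop("at least 2 folds are required")
  structure(list(task = task, feature_set = feature_set, reduction = reduction,
                 classifier = classifier, oversampling = oversampling,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 hyperopt_budget = hyperopt_budget,
                 variance_target = variance_target,
                 cap_pre_oversampling = cap_pre_oversampling,
                 select_alpha = select_alpha, max_selected = max_selected,
                 features = features, oversample_amount = oversample_amount,
                 smote_k = smote_k),
            class = "experiment_config")
}

#' Stratified k-fold assignments
#'
#' Shuffles each class independently and deals its members round-robin, so
#' per-class fold counts differ by at most one; fold starting offsets rotate
#' across classes to balance total fold sizes.
#'
#' @param labels Factor (or vector) of class labels.
#' @param k Number of folds (>= 2).
#' @param seed Optional seed (uses the current RNG stream when NULL).
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_kfold <- function(labels, k = 3, seed = NULL) {
  labels <- factor(labels)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  counts <- table(labels)
  small <- names(counts)[counts < k]
  if (length(small))
    stop("class(es) smaller than k folds: ", paste(small, collapse = ", "))
  assign_folds <- function() {
    fold <- integer(length(labels))
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx) %% k
    }
    fold
  }
  if (is.null(seed)) assign_folds() else with_seed(seed, assign_folds())
}

#' PCA dimensionality reduction fitted on the training fold only
#'
#' Standardises by training means/SDs, takes the smallest number of
#' principal components reaching the cumulative-variance target, capped at
#' `cap` (the N_min - 1 rule, N_min the smallest group size), and projects
#' the test fold with the training loadings — no test-fold leakage.
#'
#' @param train,test Numeric feature matrices.
#' @param variance_target Cumulative variance fraction (default 0.95).
#' @param cap Maximum number of components (default: no cap).
#' @return List: `train`, `test` (score matrices), `n_components`,
#'   `cum_variance`, `rotation`, `center`, `scale`.
#' @export
pca_reduce <- function(train, test = NULL, variance_target = 0.95,
                       cap = Inf) {
  train <- as.matrix(train)
  if (ncol(train) < 1) stop("at least one feature is required")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  tr <- sweep(sweep(train, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(tr, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  nz <- sum(ev > 1e-12)
  cumvar <- cumsum(ev) / sum(ev)
  m_var <- which(cumvar >= variance_target)[1]
  if (is.na(m_var)) m_var <- nz
  m <- max(1L, min(m_var, nz, floor(cap)))
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  out <- list(train = tr %*% rot, n_components = m,
              cum_variance = cumvar[m], rotation = rot,
              center = ctr, scale = scl)
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2, ctr), 2, scl, "/")
    out$test <- te %*% rot
  }
  out
}

#' Fold-wise univariate feature selection
#'
#' Runs the univariate battery (gated omnibus test, Bonferroni over the
#' features offered) on the training fold only and keeps the significant
#' features ranked by their best pairwise discrimination
#' (max over class pairs of max(AUC, 1 - AUC)); when nothing survives
#' Bonferroni the single best-ranked feature is kept.
#'
#' @param train_x Training feature matrix (named columns).
#' @param train_y Training labels.
#' @param alpha Base significance level.
#' @param max_features Optional cap on the number kept.
#' @return Character vector of selected feature names (ranked).
#' @export
univariate_select <- function(train_x, train_y, alpha = 0.05,
                              max_features = NULL) {
  train_x <- as.matrix(train_x)
  y <- droplevels(factor(train_y))
  p <- ncol(train_x)
  lev <- levels(y)
  pairs <- utils::combn(lev, 2)
  stats_ <- lapply(colnames(train_x), function(f) {
    v <- train_x[, f]
    cmp <- tryCatch(compare_groups(v, y, n_features_tested = p, alpha = alpha),
                    error = function(e) list(p = 1,
                                             significant_bonferroni = FALSE))
    aucs <- vapply(seq_len(ncol(pairs)), function(j) {
      sel <- y %in% pairs[, j]
      if (length(unique(y[sel])) < 2) return(0.5)
      a <- roc_auc(v[sel], droplevels(y[sel]), positive = pairs[2, j])
      max(a, 1 - a)
    }, numeric(1))
    data.frame(feature = f, significant = cmp$significant_bonferroni,
               auc_rank = max(aucs), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, stats_)
  tab <- tab[order(-tab$auc_rank), ]
  keep <- tab$feature[tab$significant]
  if (!length(keep)) keep <- tab$feature[1]
  if (!is.null(max_features)) keep <- utils::head(keep, max_features)
  keep
}

feature_subset <- function(table, feature_set, features = NULL) {
  all_feats <- intersect(feature_column_names(), names(table))
  if (!is.null(features)) {
    missing <- setdiff(features, names(table))
    if (length(missing))
      stop("feature(s) not in table: ", paste(missing, collapse = ", "))
    return(features)
  }
  switch(feature_set,
         all = all_feats,
         roi = c(grep("_ROI_", all_feats, value = TRUE),
                 intersect("tumour_volume_cm3", all_feats)),
         wb = grep("_WB_", all_feats, value = TRUE))
}

#' Classification metrics from pooled cross-validated predictions
#'
#' @param truth,pred Factors on the same levels.
#' @return List: `bar` (balanced accuracy, %, the mean per-class recall),
#'   `f_stat` (macro-averaged F1), `macro_precision` (%), `per_class`
#'   data.frame (precision %, recall %, F1), `confusion` (rows = truth).
#' @export
classification_metrics <- function(truth, pred) {
  lev <- levels(truth)
  pred <- factor(pred, levels = lev)
  cm <- table(truth = truth, pred = pred)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  prec_den <- colSums(cm)
  precision <- ifelse(prec_den > 0, diag(cm) / pmax(prec_den, 1), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  list(bar = 100 * mean(recall),
       f_stat = mean(f1),
       macro_precision = 100 * mean(precision),
       per_class = data.frame(class = lev,
                              precision_pct = 100 * precision,
                              recall_pct = 100 * recall,
                              f1 = f1, row.names = NULL),
       confusion = cm)
}

#' Run one stratified cross-validated classification experiment
#'
#' Per outer fold: oversampling (training rows only), training-fold
#' standardisation, dimensionality reduction (PCA to the variance target
#' capped at N_min - 1, or fold-wise univariate selection), inner-CV
#' hyperparameter tuning maximising training macro one-vs-rest AUC, fitting,
#' and prediction of the untouched test fold. Test predictions are pooled
#' across folds before computing metrics. Every source of randomness derives
#' from `config$seed`.
#'
#' @param table Feature table ([build_feature_table()] /
#'   [simulate_feature_table()]).
#' @param config An [experiment_config()].
#' @return List of class `cv_report`: `bar`, `f_stat`, `macro_precision`,
#'   `per_class`, `confusion`, `predictions` (pooled, with fold ids),
#'   `fold_details` (selected features / components and tuned
#'   hyperparameters per fold) and the `config`.
#' @export
train_and_evaluate <- function(table, config) {
  stopifnot(inherits(config, "experiment_config"))
  feats <- feature_subset(table, config$feature_set, config$features)
  x <- as.matrix(table[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  y <- if (config$task == "type") droplevels(factor(table$label))
       else droplevels(factor(table$grade))
  scaled_learner <- config$classifier %in% c("svm", "knn", "neural_net")

  with_seed(config$seed, {
    folds <- stratified_kfold(y, config$n_folds)
    pooled <- data.frame(row = integer(0), fold = integer(0),
                         truth = character(0), pred = character(0),
                         stringsAsFactors = FALSE)
    fold_details <- list()
    for (f in seq_len(config$n_folds)) {
      tr <- folds != f; te <- folds == f
      tr_x <- x[tr, , drop = FALSE]; tr_y <- y[tr]
      te_x <- x[te, , drop = FALSE]
      n_min_pre <- min(table(tr_y))

      if (config$oversampling != "none") {
        target <- if (config$task == "type") "ependymoma"
                  else names(which.min(table(tr_y)))
        os <- oversample(tr_x, tr_y, config$oversampling, target,
                         amount = config$oversample_amount,
                         k_neighbours = config$smote_k)
        tr_x <- os$x; tr_y <- os$y
      }

      detail <- list(fold = f)
      if (config$reduction == "pca") {
        cap <- (if (config$cap_pre_oversampling) n_min_pre
                else min(table(tr_y))) - 1
        red <- pca_reduce(tr_x, te_x, config$variance_target, cap)
        fit_x <- red$train; pred_x <- red$test
        detail$n_components <- red$n_components
      } else if (config$reduction == "univariate") {
        sel <- univariate_select(tr_x, tr_y, alpha = config$select_alpha,
                                 max_features = config$max_selected)
        detail$selected <- sel
        fit_x <- tr_x[, sel, drop = FALSE]
        pred_x <- te_x[, sel, drop = FALSE]
      } else {
        fit_x <- tr_x; pred_x <- te_x
      }

      if (scaled_learner && config$reduction != "pca") {
        ctr <- colMeans(fit_x)
        scl <- apply(fit_x, 2, stats::sd); scl[scl < 1e-12] <- 1
        fit_x <- sweep(sweep(fit_x, 2, ctr), 2, scl, "/")
        pred_x <- sweep(sweep(pred_x, 2, ctr), 2, scl, "/")
      }

      params <- tune_learner(config$classifier, fit_x, tr_y,
                             config$hyperopt_budget)
      detail$params <- params
      if (config$classifier == "knn") detail$k <- knn_k_rule(nrow(fit_x))
      fit <- fit_learner(config$classifier, fit_x, tr_y, params)
      pr <- predict_learner(fit, pred_x)
      pooled <- rbind(pooled, data.frame(
        row = which(te), fold = f, truth = as.character(y[te]),
        pred = as.character(pr$class), stringsAsFactors = FALSE))
      fold_details[[f]] <- detail
    }
    lev <- levels(y)
    met <- classification_metrics(factor(pooled$truth, levels = lev),
                                  factor(pooled$pred, levels = lev))
    structure(c(met, list(predictions = pooled, fold_details = fold_details,
                          config = config)),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: task=%s  set=%s  reduction=%s  classifier=%s  oversampling=%s\n",
              x$config$task, x$config$feature_set, x$config$reduction,
              x$config$classifier, x$config$oversampling))
  cat(sprintf("  BAR = %.1f%%   macro F = %.2f   macro precision = %.1f%%\n",
              x$bar, x$f_stat, x$macro_precision))
  print(x$per_class, digits = 3)
  invisible(x)
}

#' Perturbation analysis: each feature paired with the ADC ROI mean
#'
#' For every feature `f` other than the base, runs the full cross-validated
#' experiment on the two-feature set {base, f} (no further reduction) and
#' reports the resulting macro precision, BAR and macro F1, ranked by
#' precision.
#'
#' @param table Feature table.
#' @param config An [experiment_config()] (its `reduction` is forced to
#'   `"none"`; its `feature_set` / `family` limits the paired candidates).
#' @param base_feature Anchor feature (default `"ADC_ROI_mean"`).
#' @param family `"roi"`, `"wb"` or `"all"`: which features are paired.
#' @return data.frame `feature`, `macro_precision_pct`, `bar_pct`, `f_stat`,
#'   sorted by precision (descending).
#' @export
perturbation_analysis <- function(table, config,
                                  base_feature = "ADC_ROI_mean",
                                  family = c("roi", "wb", "all")) {
  family <- match.arg(family)
  if (!base_feature %in% names(table))
    stop("base feature '", base_feature, "' not in table")
  cands <- setdiff(feature_subset(table, family), base_feature)
  rows <- lapply(cands, function(f) {
    cfg <- config
    cfg$reduction <- "none"
    cfg$features <- c(base_feature, f)
    rep_ <- train_and_evaluate(table, cfg)
    data.frame(feature = f, macro_precision_pct = rep_$macro_precision,
               bar_pct = rep_$bar, f_stat = rep_$f_stat,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$macro_precision_pct), , drop = FALSE]
}
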