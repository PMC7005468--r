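test_that("stratified folds partition each class near-evenly", {
  labels <- rep(tumour_classes(), times = c(22, 17, 10))
  folds <- stratified_kfold(labels, 3, seed = 2)
  expect_setequal(unique(folds), 1:3)
  expect_length(folds, 49)
  counts <- table(labels, folds)
  expect_true(all(apply(counts, 1, function(r) diff(range(r)) <= 1)))
  expect_equal(sort(as.vector(counts["pilocytic_astrocytoma", ])), c(7, 7, 8))
  expect_equal(sort(as.vector(counts["medulloblastoma", ])), c(5, 6, 6))
  expect_equal(sort(as.vector(counts["ependymoma", ])), c(3, 3, 4))
  expect_error(stratified_kfold(labels, 1), "at least 2")
  expect_error(stratified_kfold(c("a", "a", "b"), 2), "b")
  expect_identical(stratified_kfold(labels, 3, seed = 2),
                   stratified_kfold(labels, 3, seed = 2))
})

test_that("PCA reduction honours the variance target and component cap", {
  with_seed(61, {
    x <- matrix(rnorm(40 * 33), 40, 33)
    red <- pca_reduce(x[1:30, ], x[31:40, ], cap = 9)
    expect_lte(red$n_components, 9)
    expect_equal(ncol(red$train), red$n_components)
    expect_equal(ncol(red$test), red$n_components)
    # two genuine directions only -> two components
    z <- matrix(rnorm(40 * 2), 40, 2)
    x2 <- cbind(z, z %*% matrix(rnorm(2 * 6), 2, 6))
    red2 <- pca_reduce(x2, variance_target = 0.999)
    expect_equal(red2$n_components, 2)
    # reconstruction error is non-increasing in the number of components
    xs <- scale(x)
    pc <- prcomp(xs, center = FALSE, scale. = FALSE)
    errs <- vapply(1:10, function(m) {
      rot <- pc$rotation[, 1:m, drop = FALSE]
      sum((xs - xs %*% rot %*% t(rot))^2)
    }, numeric(1))
    expect_true(all(diff(errs) <= 1e-8))
  })
})

test_that("fold-wise univariate selection finds separators, never test rows", {
  with_seed(62, {
    x <- matrix(rnorm(45 * 5), 45,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- rep(c("a", "b", "c"), each = 15)
    x[, 3] <- as.numeric(factor(y)) * 10 + rnorm(45, 0, 0.1)  # perfect separator
    sel <- univariate_select(x, y)
    expect_equal(sel[1], "f3")
  })
  # permuted labels: selection generalises at chance level on held-out data
  with_seed(63, {
    aucs <- replicate(20, {
      x <- matrix(rnorm(40 * 6), 40,
                  dimnames = list(NULL, paste0("f", 1:6)))
      y <- factor(rep(c("a", "b"), each = 20)[sample.int(40)])
      tr <- 1:30; te <- 31:40
      s <- univariate_select(x[tr, ], y[tr])[1]
      if (nlevels(droplevels(y[te])) < 2) NA_real_
      else roc_auc(x[te, s], y[te], positive = "b")
    })
    expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.12)
  })
})

test_that("selected feature sets differ across folds on a realistic cohort", {
  tab <- simulate_feature_table(seed = 4)
  rep_ <- train_and_evaluate(tab, experiment_config(
    "type", "univariate_all", classifier = "knn", seed = 4))
  sels <- lapply(rep_$fold_details, `[[`, "selected")
  expect_true(length(unique(sels)) > 1)
})

test_that("oversampling doubles the minority and leaves inputs untouched", {
  with_seed(71, {
    x <- matrix(rnorm(18 * 4), 18, dimnames = list(NULL, paste0("f", 1:4)))
    y <- factor(rep(c("pilocytic_astrocytoma", "medulloblastoma",
                      "ependymoma"), times = c(7, 5, 6)))
    for (m in c("replicate", "smote")) {
      os <- oversample(x, y, m, "ependymoma")
      expect_equal(sum(os$y == "ependymoma"), 12)
      expect_equal(nrow(os$x), 24)
      expect_identical(os$x[1:18, ], x)       # originals untouched
    }
    # SMOTE points are coordinate-wise convex combinations of minority rows
    os <- oversample(x, y, "smote", "ependymoma", seed = 5)
    minority <- x[y == "ependymoma", ]
    new_pts <- os$x[19:24, ]
    for (j in seq_len(nrow(new_pts))) {
      expect_true(all(new_pts[j, ] >= apply(minority, 2, min) - 1e-12))
      expect_true(all(new_pts[j, ] <= apply(minority, 2, max) + 1e-12))
    }
    ident <- oversample(x, y, "none")
    expect_identical(ident$x, x)
    y2 <- factor(rep(c("a", "b"), c(17, 1)))
    expect_error(oversample(x, y2, "smote", "b"), "at least 2")
  })
})

test_that("the kNN k rule rounds the root and avoids even k", {
  expect_equal(knn_k_rule(25), 5)
  expect_equal(knn_k_rule(16), 3)   # 4 is even -> 3
  expect_equal(knn_k_rule(36), 5)   # 6 -> 5
  expect_equal(knn_k_rule(2), 1)
  expect_equal(knn_k_rule(33), 5)   # round(5.74) = 6 -> 5
})

test_that("grade labels map PA to low and the rest to high", {
  labs <- rep(tumour_classes(), times = c(22, 17, 10))
  g <- grade_task_labels(labs)
  expect_equal(sum(g == "low"), 22)
  expect_equal(sum(g == "high"), 27)
  expect_equal(unique(as.character(grade_task_labels(
    rep("pilocytic_astrocytoma", 5)))), "low")
  expect_error(grade_task_labels("astrocytoma"), "unknown")
})

test_that("perfectly separated classes give saturated metrics", {
  prof <- default_class_profile()
  # push class means 10 SDs apart on one feature, tiny SDs elsewhere
  prof$sd <- prof$sd * 0.01
  prof$mean[prof$feature == "ADC_ROI_mean"] <- c(10, 20, 30)[
    match(prof$class[prof$feature == "ADC_ROI_mean"],
          c("pilocytic_astrocytoma", "ependymoma", "medulloblastoma"))]
  tab <- simulate_feature_table(profile = prof, seed = 9)
  rep_ <- train_and_evaluate(tab, experiment_config(
    "type", "univariate_all", classifier = "knn", seed = 9))
  expect_equal(rep_$bar, 100)
  expect_equal(rep_$f_stat, 1.0)
  expect_true(all(rep_$per_class$precision_pct == 100))
})

test_that("metrics follow their definitions on a hand confusion case", {
  truth <- factor(c("a", "a", "a", "b", "b", "c"), levels = c("a", "b", "c"))
  pred <- factor(c("a", "a", "b", "b", "b", "a"), levels = c("a", "b", "c"))
  m <- classification_metrics(truth, pred)
  # recalls: 2/3, 1, 0 -> BAR = 55.6%; majority-style degenerate rows handled
  expect_equal(m$bar, 100 * mean(c(2 / 3, 1, 0)), tolerance = 1e-9)
  expect_equal(as.vector(rowSums(m$confusion)), c(3, 2, 1))
  prec <- c(2 / 3, 2 / 3, 0)
  expect_equal(m$per_class$precision_pct, 100 * prec, tolerance = 1e-9)
  # a constant classifier scores 1/k balanced accuracy
  all_a <- factor(rep("a", 6), levels = c("a", "b", "c"))
  expect_equal(classification_metrics(truth, all_a)$bar, 100 / 3,
               tolerance = 1e-9)
})

test_that("fitting never looks at the test fold", {
  tab <- simulate_feature_table(seed = 12)
  cfg <- experiment_config("type", "univariate_all", classifier = "adaboost",
                           seed = 12)
  y <- factor(tab$label)
  folds <- stratified_kfold(y, 3, seed = cfg$seed)
  r1 <- train_and_evaluate(tab, cfg)
  tab2 <- tab
  tab2[folds == 1, feature_column_names()] <- 0  # vandalise fold-1 test rows
  r2 <- train_and_evaluate(tab2, cfg)
  # fold 1 trains on folds 2+3 (unchanged): identical selection and params
  expect_identical(r1$fold_details[[1]]$selected,
                   r2$fold_details[[1]]$selected)
  expect_identical(r1$fold_details[[1]]$params, r2$fold_details[[1]]$params)
  # and the input table is never mutated by a run
  h1 <- serialize(tab, NULL)
  invisible(train_and_evaluate(tab, cfg))
  expect_identical(serialize(tab, NULL), h1)
})

test_that("perturbation analysis ranks informative pairings above noise", {
  prof <- default_class_profile()
  tab <- simulate_feature_table(seed = 14, profile = prof)
  # a pure-noise column and a near-copy of the base feature
  cfg <- experiment_config("type", "all", classifier = "knn", seed = 14)
  res <- perturbation_analysis(tab, cfg, family = "roi")
  expect_equal(nrow(res),
               length(pedmri:::feature_subset(tab, "roi")) - 1)
  expect_true(all(c("feature", "macro_precision_pct") %in% names(res)))
  res2 <- perturbation_analysis(tab, cfg, family = "roi")
  expect_identical(res, res2)      # deterministic under the fixed seed
})

test_that("every learner family trains and predicts on the cohort", {
  tab <- simulate_feature_table(seed = 20)
  for (clf in c("adaboost", "random_forest", "svm", "knn", "neural_net")) {
    cfg <- experiment_config("grade", "roi", reduction = "none",
                             classifier = clf, seed = 20,
                             hyperopt_budget = 1)
    rep_ <- train_and_evaluate(tab, cfg)
    expect_true(rep_$bar >= 0 && rep_$bar <= 100)
    expect_equal(nrow(rep_$predictions), nrow(tab))
    expect_setequal(rep_$predictions$row, seq_len(nrow(tab)))
  }
})
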