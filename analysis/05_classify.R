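#!/usr/bin/env Rscript
# Cross-validated classification on the 49-subject cohort: stratified 3-fold
# CV over two tasks (three tumour types; low/high grade), comparing PCA
# dimensionality reduction (95% variance, N_min-1 cap) against fold-wise
# univariate feature selection, across the five learner families, plus the
# ependymoma oversampling arms.

library(pedmri)

tab <- read_feature_table("results/feature_cohort.csv")
seed <- 20260930
classifiers <- c("adaboost", "random_forest", "svm", "knn", "neural_net")
arms <- list(all_pca = list(feature_set = "all", reduction = "pca"),
             roi_pca = list(feature_set = "roi", reduction = "pca"),
             wb_pca = list(feature_set = "wb", reduction = "pca"),
             univariate_roi = list(feature_set = "univariate_roi"),
             univariate_all = list(feature_set = "univariate_all"))

run_arm <- function(task, arm_name, clf, oversampling = "none") {
  a <- arms[[arm_name]]
  cfg <- do.call(experiment_config, c(list(task = task, classifier = clf,
                                           oversampling = oversampling,
                                           seed = seed), a))
  r <- train_and_evaluate(tab, cfg)
  data.frame(task = task, arm = arm_name, classifier = clf,
             oversampling = oversampling, bar_pct = r$bar,
             f_stat = r$f_stat, macro_precision_pct = r$macro_precision)
}

rows <- list()
for (task in c("type", "grade"))
  for (arm in names(arms))
    for (clf in classifiers)
      rows[[length(rows) + 1]] <- run_arm(task, arm, clf)
res <- do.call(rbind, rows)
write.csv(res, "results/classification.csv", row.names = FALSE)

cat("Best arm per task (by BAR):\n")
for (task in c("type", "grade")) {
  r <- res[res$task == task, ]
  b <- r[which.max(r$bar_pct), ]
  cat(sprintf("  %-5s %s + %s: BAR %.0f%%, macro F %.2f, precision %.0f%%\n",
              task, b$arm, b$classifier, b$bar_pct, b$f_stat,
              b$macro_precision_pct))
  for (arm in names(arms)) {
    ra <- r[r$arm == arm, ]
    cat(sprintf("    %-15s best-of-learners BAR %.0f%%\n", arm,
                max(ra$bar_pct)))
  }
}

# oversampling comparison on the strongest type arms
os_rows <- list()
for (os in c("none", "replicate", "smote"))
  for (arm in c("all_pca", "univariate_all"))
    os_rows[[length(os_rows) + 1]] <- run_arm("type", arm, "adaboost", os)
os_res <- do.call(rbind, os_rows)
write.csv(os_res, "results/oversampling.csv", row.names = FALSE)
cat("\nEpendymoma oversampling (+100%), AdaBoost, type task:\n")
print(os_res[, c("arm", "oversampling", "bar_pct", "f_stat")],
      row.names = FALSE, digits = 3)
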