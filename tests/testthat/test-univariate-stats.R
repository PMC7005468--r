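test_that("normality gate picks ANOVA for normal groups, KW otherwise", {
  anova_picks <- with_seed(31, {
    vapply(1:40, function(i) {
      v <- rnorm(150); g <- rep(letters[1:3], each = 50)
      normality_gate(v, g) == "anova"
    }, logical(1))
  })
  expect_gte(mean(anova_picks), 0.7)   # SW size ~5% per group under the null
  kw_picks <- with_seed(32, {
    vapply(1:40, function(i) {
      v <- c(rnorm(100), rlnorm(50, 0, 1.5)); g <- rep(letters[1:3], each = 50)
      normality_gate(v, g) == "kruskal"
    }, logical(1))
  })
  expect_gte(mean(kw_picks), 0.9)
  # groups too small for Shapiro-Wilk fall back to the rank test
  expect_equal(as.character(normality_gate(c(1, 2, 5, 6, 3, 8),
                                           c("a", "a", "b", "b", "b", "b"))),
               "kruskal")
})

test_that("group comparison rejects separated groups and honours Bonferroni", {
  with_seed(41, {
    v <- c(rnorm(15, 0), rnorm(15, 3), rnorm(15, 6))
    g <- rep(c("a", "b", "c"), each = 15)
    res <- compare_groups(v, g, n_features_tested = 33)
    expect_lt(res$p, 0.05 / 33)
    expect_true(res$significant_bonferroni)
    expect_equal(res$alpha_adjusted, 0.05 / 33)
    expect_equal(nrow(res$posthoc), 3)
    expect_true(all(res$posthoc$p_adj <= 1 & res$posthoc$p_adj >= 0))
  })
  # constant feature: p = 1 convention
  resc <- compare_groups(rep(2, 30), rep(c("a", "b", "c"), 10))
  expect_equal(resc$p, 1)
  expect_false(resc$significant_bonferroni)
  expect_error(compare_groups(1:10, rep("a", 10)), "two groups")
})

test_that("a feature just under the adjusted alpha is not flagged", {
  with_seed(43, {
    v <- c(rnorm(20, 0), rnorm(20, 0.9))   # modest effect
    g <- rep(c("a", "b"), each = 20)
    res <- compare_groups(v, g, n_features_tested = 1)
    res33 <- compare_groups(v, g, n_features_tested = 33)
    expect_equal(res$p, res33$p)
    if (res$p > 0.05 / 33 && res$p < 0.05) {
      expect_true(res$significant_bonferroni)
      expect_false(res33$significant_bonferroni)
    }
  })
})

test_that("rank AUC matches definitions and the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       rep(c("n", "p"), each = 3), positive = "p"), 1)
  expect_equal(roc_auc(rep(5, 10), rep(c("n", "p"), 5), positive = "p"), 0.5)
  with_seed(51, {
    for (i in 1:10) {
      v <- sample(1:8, 20, replace = TRUE)   # ties on purpose
      lab <- factor(sample(c("n", "p"), 20, replace = TRUE,
                           prob = c(0.5, 0.5)))
      if (nlevels(droplevels(lab)) < 2) next
      expect_equal(roc_auc(v, lab, positive = "p"),
                   brute_auc(v, lab == "p"), tolerance = 1e-12)
      # orientation: AUC(v) + AUC(-v) = 1 exactly
      expect_equal(roc_auc(v, lab, positive = "p") +
                     roc_auc(-v, lab, positive = "p"), 1)
    }
  })
  expect_error(roc_auc(1:5, rep("p", 5)), "two classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  with_seed(53, {
    v <- c(rnorm(25, 0), rnorm(15, 0.8))
    lab <- factor(rep(c("n", "p"), c(25, 15)), levels = c("n", "p"))
    ours <- roc_auc(v, lab, positive = "p")
    ref <- as.numeric(pROC::auc(pROC::roc(lab, v, levels = c("n", "p"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("Kruskal-Wallis p is invariant under monotone transforms", {
  with_seed(52, {
    v <- rlnorm(60); g <- rep(c("a", "b", "c"), 20)
    p1 <- kruskal.test(v, factor(g))$p.value
    p2 <- kruskal.test(exp(v / 2), factor(g))$p.value
    expect_equal(p1, p2)
    # and the gated battery therefore agrees feature-wise
    r1 <- compare_groups(v, g)
    r2 <- compare_groups(log(v), g)
    if (r1$test == "kruskal" && r2$test == "kruskal")
      expect_equal(r1$p, r2$p)
  })
})

test_that("the univariate battery flags the profiled features on a cohort", {
  tab <- simulate_feature_table(seed = 6)
  res <- run_univariate_battery(tab, "type")
  expect_equal(nrow(res), 33)
  expect_true(all(c("feature", "test", "p", "significant_bonferroni",
                    "auc_max") %in% names(res)))
  # the strongest profiled separators should survive Bonferroni
  expect_true(res$significant_bonferroni[res$feature == "ADC_ROI_mean"])
  # AUC below 0.5 is reported as-is in the pairwise columns
  auc_cols <- grep("^auc_.*_vs_", names(res), value = TRUE)
  expect_true(any(as.matrix(res[, auc_cols]) < 0.5))
  resg <- run_univariate_battery(tab, "grade")
  expect_equal(sum(grepl("^auc_low_vs_high$", names(resg))), 1)
})
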