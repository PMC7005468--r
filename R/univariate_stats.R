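#' Choose the omnibus test by per-group normality
#'
#' Runs a Shapiro-Wilk test in every group; parametric one-way ANOVA is used
#' only when every group is consistent with normality at `alpha`, otherwise
#' (or when a group is too small or constant for the test) the Kruskal-Wallis
#' rank test is used.
#'
#' @param values Numeric vector.
#' @param groups Factor (or coercible) of group membership.
#' @param alpha Normality test level (default 0.05).
#' @return `"anova"` or `"kruskal"`, with per-group Shapiro p-values in the
#'   `"shapiro_p"` attribute.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ps <- vapply(levels(groups), function(g) {
    x <- values[groups == g & is.finite(values)]
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0)
      return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  choice <- if (any(is.na(ps)) || any(ps <= alpha)) "kruskal" else "anova"
  attr(choice, "shapiro_p") <- ps
  choice
}

# Dunn's rank-based post-hoc z-tests with tie correction, Bonferroni-adjusted
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  keep <- is.finite(values)
  values <- values[keep]; groups <- droplevels(groups[keep])
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_adj <- pmin(out$p * m, 1)
  out
}

#' Omnibus group comparison with gated test choice and post-hoc pairs
#'
#' ANOVA with Tukey HSD when every group passes the normality gate, otherwise
#' Kruskal-Wallis with a Dunn rank post-hoc (Bonferroni over pairs); a flag
#' forces Tukey after Kruskal-Wallis for strict replication of pipelines that
#' pair the two. Feature-level significance is Bonferroni-adjusted across the
#' `n_features_tested` features of the battery.
#'
#' @param values Numeric feature vector.
#' @param groups Group labels (factor).
#' @param n_features_tested Number of features in the multiple-comparison
#'   family (default 1).
#' @param alpha Base significance level.
#' @param posthoc `"auto"` (Tukey under ANOVA, Dunn under Kruskal-Wallis) or
#'   `"tukey"` to force Tukey HSD.
#' @return List: `test`, `p`, `significant_bonferroni`, `alpha_adjusted`,
#'   `posthoc` (data.frame `group1`, `group2`, `p`, `p_adj`).
#' @export
compare_groups <- function(values, groups, n_features_tested = 1,
                           alpha = 0.05, posthoc = c("auto", "tukey")) {
  posthoc <- match.arg(posthoc)
  groups <- factor(groups)
  if (nlevels(droplevels(groups[is.finite(values)])) < 2)
    stop("at least two groups with data are required")
  alpha_adj <- alpha / n_features_tested
  keep <- is.finite(values)
  v <- values[keep]; g <- droplevels(groups[keep])
  if (stats::sd(v) == 0) {
    lev <- levels(g); pairs <- utils::combn(lev, 2)
    ph <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = 1,
                     p_adj = 1, stringsAsFactors = FALSE)
    return(list(test = "constant", p = 1, significant_bonferroni = FALSE,
                alpha_adjusted = alpha_adj, posthoc = ph))
  }
  test <- normality_gate(v, g, alpha)
  if (test == "anova") {
    fit <- stats::aov(v ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    ph <- data.frame(group1 = sub("-.*", "", rownames(tk)),
                     group2 = sub(".*-", "", rownames(tk)),
                     p = tk[, "p adj"], p_adj = tk[, "p adj"],
                     stringsAsFactors = FALSE)
  } else {
    p <- stats::kruskal.test(v, g)$p.value
    if (posthoc == "tukey") {
      fit <- stats::aov(v ~ g)
      tk <- stats::TukeyHSD(fit)$g
      ph <- data.frame(group1 = sub("-.*", "", rownames(tk)),
                       group2 = sub(".*-", "", rownames(tk)),
                       p = tk[, "p adj"], p_adj = tk[, "p adj"],
                       stringsAsFactors = FALSE)
    } else {
      ph <- dunn_posthoc(v, g)
    }
  }
  # canonical pair order (by factor level) so batteries align across features
  lev <- levels(g)
  flip <- match(ph$group1, lev) > match(ph$group2, lev)
  tmp <- ph$group1[flip]; ph$group1[flip] <- ph$group2[flip]
  ph$group2[flip] <- tmp
  ph <- ph[order(match(ph$group1, lev), match(ph$group2, lev)), ]
  rownames(ph) <- NULL
  list(test = as.character(test), p = p,
       significant_bonferroni = is.finite(p) && p < alpha_adj,
       alpha_adjusted = alpha_adj, posthoc = ph)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' \eqn{AUC = U / (n_1 n_0)} with ties counted one half. Orientation is fixed
#' by `positive`: higher values of the feature in the positive class give
#' AUC > 0.5; values below 0.5 are reported as-is, never folded.
#'
#' @param values Numeric vector.
#' @param labels Binary labels (factor or vector with exactly two levels).
#' @param positive The positive-class label (default: second factor level).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels, positive = NULL) {
  labels <- factor(labels)
  keep <- is.finite(values)
  values <- values[keep]; labels <- droplevels(labels[keep])
  if (nlevels(labels) != 2)
    stop("roc_auc requires exactly two classes present")
  if (is.null(positive)) positive <- levels(labels)[2]
  if (!positive %in% levels(labels)) stop("unknown positive class")
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate feature battery over a feature table
#'
#' For every feature column: the gated omnibus test across the task's groups,
#' Bonferroni-adjusted significance over all features tested, the post-hoc
#' pairwise p-values, and rank AUCs (the single AUC for the binary grade
#' task; every pairwise one-vs-one AUC, and their maximum, for the
#' three-class type task).
#'
#' @param table Feature table from [build_feature_table()] or
#'   [simulate_feature_table()].
#' @param task `"type"` (three classes) or `"grade"` (low/high).
#' @param features Feature columns to test (default: all 33).
#' @param alpha Base level (default 0.05).
#' @param posthoc Passed to [compare_groups()].
#' @return data.frame, one row per feature: `feature`, `test`, `p`,
#'   `significant_bonferroni`, `auc_max`, one `auc_*` column per class pair,
#'   and one `p_<pair>` column per post-hoc pair.
#' @export
run_univariate_battery <- function(table, task = c("type", "grade"),
                                   features = NULL, alpha = 0.05,
                                   posthoc = c("auto", "tukey")) {
  task <- match.arg(task)
  posthoc <- match.arg(posthoc)
  if (is.null(features)) features <- intersect(feature_column_names(),
                                               names(table))
  y <- if (task == "type") factor(table$label) else factor(table$grade)
  lev <- levels(droplevels(y))
  pairs <- utils::combn(lev, 2)
  res <- lapply(features, function(f) {
    v <- table[[f]]
    cmp <- compare_groups(v, y, n_features_tested = length(features),
                          alpha = alpha, posthoc = posthoc)
    aucs <- vapply(seq_len(ncol(pairs)), function(j) {
      sel <- y %in% pairs[, j]
      roc_auc(v[sel], droplevels(y[sel]), positive = pairs[2, j])
    }, numeric(1))
    names(aucs) <- paste0("auc_", pairs[1, ], "_vs_", pairs[2, ])
    php <- cmp$posthoc$p_adj
    names(php) <- paste0("p_", cmp$posthoc$group1, "_vs_", cmp$posthoc$group2)
    c(list(feature = f, test = cmp$test, p = cmp$p,
           significant_bonferroni = cmp$significant_bonferroni,
           auc_max = max(aucs, 1 - aucs)),
      as.list(aucs), as.list(php))
  })
  out <- do.call(rbind, lapply(res, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
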