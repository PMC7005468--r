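#!/usr/bin/env Rscript
# Perturbation analysis: pair every other feature with the tumour-ROI mean
# ADC, rerun the cross-validated classifier on each two-feature set, and
# rank the pairings by macro precision — separately for the ROI and
# whole-brain feature families.

library(pedmri)

tab <- read_feature_table("results/feature_cohort.csv")
cfg <- experiment_config("type", "all", classifier = "adaboost",
                         seed = 20260930, hyperopt_budget = 1)

for (fam in c("roi", "wb")) {
  res <- perturbation_analysis(tab, cfg, base_feature = "ADC_ROI_mean",
                               family = fam)
  out <- sprintf("results/perturbation_%s.csv", fam)
  write.csv(res, out, row.names = FALSE)
  cat(sprintf("\n%s family (%d pairings, %s); top pairings with ADC ROI mean:\n",
              toupper(fam), nrow(res), out))
  for (i in seq_len(min(5, nrow(res))))
    cat(sprintf("  + %-22s precision %.0f%%  BAR %.0f%%\n",
                res$feature[i], res$macro_precision_pct[i], res$bar_pct[i]))
}
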