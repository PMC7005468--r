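#!/usr/bin/env Rscript
# Build the subjects-by-features table from the quantified phantom maps
# (33 first-order features: 4 maps x {tumour ROI, whole brain} x 4 moments,
# plus tumour volume), and summarise the full-size feature-level cohort per
# class in the style of a univariate group table.

library(pedmri)

man_path <- "results/cohort/manifest.csv"
if (!file.exists(man_path))
  stop("run analysis/01_simulate.R and analysis/02_quantify.R first")
man <- load_manifest(man_path)

subjects <- lapply(seq_len(nrow(man)), function(i) read_subject(man, i))
q <- quantify_cohort(subjects)
tab_img <- build_feature_table(subjects, q$maps, q$adc)
write_feature_table(tab_img, "results/features_imaging.csv")
cat("Imaging feature table:", nrow(tab_img), "subjects x",
    length(feature_column_names()), "features -> results/features_imaging.csv\n")

# class-wise mean +/- SD summary of the 49-subject feature-level cohort
tab <- read_feature_table("results/feature_cohort.csv")
summ <- do.call(rbind, lapply(feature_column_names(), function(f) {
  row <- data.frame(feature = f)
  for (cl in levels(tab$label)) {
    v <- tab[[f]][tab$label == cl]
    row[[paste0(cl, "_mean")]] <- mean(v)
    row[[paste0(cl, "_sd")]] <- sd(v)
  }
  row
}))
write.csv(summ, "results/group_summary.csv", row.names = FALSE)
cat("\nClass summary (mean +/- SD) of key features:\n")
for (f in c("ADC_ROI_mean", "ADC_WB_mean", "CCBV_WB_mean",
            "tumour_volume_cm3")) {
  r <- summ[summ$feature == f, ]
  cat(sprintf("  %-18s PA %.2f+/-%.2f  MB %.2f+/-%.2f  EP %.2f+/-%.2f\n", f,
              r$pilocytic_astrocytoma_mean, r$pilocytic_astrocytoma_sd,
              r$medulloblastoma_mean, r$medulloblastoma_sd,
              r$ependymoma_mean, r$ependymoma_sd))
}
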