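#!/usr/bin/env Rscript
# Simulate the study cohorts.
#
# Two artefacts:
#  * a small voxel-level phantom cohort (NIfTI volumes + manifest) used to
#    demonstrate the full image-quantification chain in 02/03 — kept small
#    because per-voxel gamma-variate fitting dominates run time;
#  * a full-size (22/17/10) feature-level cohort drawn directly from the
#    class profile, used by the statistics and classification analyses.

library(pedmri)

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

cfg <- cohort_config(n_per_class = c(pilocytic_astrocytoma = 4,
                                     medulloblastoma = 3,
                                     ependymoma = 3),
                     grid_shape = c(16, 16, 10), noise_sd = 0.5, seed = 20260930)
write_cohort_config(cfg, file.path(res_dir, "cohort_config.yaml"))
subjects <- generate_cohort(cfg)
man <- write_cohort(subjects, file.path(res_dir, "cohort"))
cat("Wrote", length(subjects), "phantom subjects to", dirname(man), "\n")
cat("Labels:", paste(table(vapply(subjects, `[[`, "", "label")),
                     collapse = "/"), "\n")

tab <- simulate_feature_table(seed = 20260930)
write_feature_table(tab, file.path(res_dir, "feature_cohort.csv"))
cat("Wrote 49-subject feature-level cohort:",
    nrow(tab), "subjects x", length(feature_column_names()), "features;",
    sum(tab$grade == "low"), "low grade /", sum(tab$grade == "high"),
    "high grade\n")
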