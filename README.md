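# pedmri

Multi-parametric MRI quantification and machine-learning classification of
paediatric brain tumours, as a tested R pipeline.

Distinguishing the three most common paediatric brain tumour types —
pilocytic astrocytoma (low grade), medulloblastoma and ependymoma (high
grade) — from presentation MRI is hard, especially for tumours that do not
enhance with contrast. Diffusion-weighted imaging (water mobility, hence
cellularity) and dynamic susceptibility contrast (DSC) perfusion imaging
(microvascular blood volume) carry complementary microstructural signal.
`pedmri` implements the full analysis chain that turns raw multi-parametric
volumes into a cross-validated tumour-type classifier, together with a
synthetic phantom cohort generator so that every stage is testable without
patient data (none are publicly deposited for this problem).

## What the pipeline computes

**DSC perfusion quantification.** Signal is converted to transverse
relaxation change, ΔR₂\*(t) = −ln(S(t)/S̄₀)/TE, taken as proportional to
contrast concentration. Each voxel's first pass is fitted with the
gamma-variate bolus model

    C(t) = A (t − t₀)^α exp(−(t − t₀)/β),   t > t₀

by Levenberg–Marquardt least squares, and uncorrected cerebral blood volume
(UCBV) is the analytic curve integral A β^(α+1) Γ(α+1). Contrast leakage
through a disrupted blood–brain barrier is estimated per voxel with the
Boxerman-style linear model

    ΔR₂*(t) ≈ K₁ R̄(t) − K₂ ∫₀ᵗ R̄(τ) dτ,

where R̄ is the mean curve of a non-enhancing reference region; K₂ is the
leakage-rate map, and corrected CBV (CCBV) comes from refitting the
leakage-restored curve. Maps are QC-masked on fit RMSE and on
|CBV| > 3.0 mL 100 g⁻¹ min⁻¹, then normalised to normal-appearing white
matter (NAWM).

**ADC mapping.** The apparent diffusion coefficient from two b-value
volumes is the exact two-point log-linear solution
ADC = ln(S_low/S_high)/(b_high − b_low).

**Features.** For each of ADC, UCBV, K₂ and CCBV, over the tumour ROI and
the whole brain: mean, SD, skewness and Pearson kurtosis, plus tumour
volume — 33 features per subject.

**Statistics.** Shapiro–Wilk-gated ANOVA (Tukey post-hoc) or
Kruskal–Wallis (Dunn post-hoc), Bonferroni correction across all features,
and rank (Mann–Whitney) AUCs.

**Classification.** Stratified 3-fold cross-validation on two tasks
(3-class type; binary grade), with either PCA (95% variance, capped at
N_min − 1 components) or fold-wise univariate feature selection; AdaBoost
(stump ensemble), random forest, RBF-SVM, kNN (k = round(√n_train)) and a
single-hidden-layer neural network; optional +100% ependymoma oversampling
(replication or SMOTE) on training folds only; metrics are balanced
accuracy (mean per-class recall), macro F1 and per-class precision.

## Worked example

```r
library(pedmri)

# 49-subject synthetic cohort (22 PA / 17 MB / 10 EP) with the package's
# default class-conditional feature distributions
tab <- simulate_feature_table(seed = 1)

res <- run_univariate_battery(tab, task = "type")
sig <- res[res$significant_bonferroni, c("feature", "test", "p", "auc_max")]
print(sig[order(sig$p), ], digits = 2, row.names = FALSE)
#>            feature  test       p auc_max
#>       ADC_ROI_mean anova 5.6e-10    0.95
#>  tumour_volume_cm3 anova 1.7e-08    0.91
#>        ADC_WB_mean anova 5.6e-06    0.91
#>       CCBV_WB_mean anova 2.5e-05    0.87
#>   ADC_ROI_skewness anova 2.9e-04    0.85

cfg <- experiment_config("type", "univariate_all",
                         classifier = "adaboost", seed = 1)
train_and_evaluate(tab, cfg)
#> cv_report: task=type  set=all  reduction=univariate  classifier=adaboost  oversampling=none
#>   BAR = 77.8%   macro F = 0.79   macro precision = 80.8%
#>                   class precision_pct recall_pct    f1
#> 1 pilocytic_astrocytoma          80.0       90.9 0.851
#> 2       medulloblastoma          87.5       82.4 0.848
#> 3            ependymoma          75.0       60.0 0.667
```

Five of the 33 features separate the simulated types after Bonferroni
correction (tumour-ROI mean ADC strongest, best pairwise AUC 0.95), and the
fold-wise univariate-selection AdaBoost classifier reaches 77.8% balanced
accuracy on this cohort — selection happens inside each training fold, so
the test folds never inform it.

The full analysis sequence lives under `analysis/` (run from the repository
root, in order): `01_simulate.R` (phantom image cohort + 49-subject feature
cohort), `02_quantify.R` (per-voxel DSC fitting, leakage correction, ADC),
`03_features.R`, `04_stats.R`, `05_classify.R` (all arms × learners, both
tasks, oversampling comparison) and `06_perturbation.R` (each feature paired
with mean ROI ADC). Each writes its tables under `results/`.

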