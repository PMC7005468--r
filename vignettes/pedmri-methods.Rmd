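---
title: "Models and methods behind the pedmri pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pedmri pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pedmri` turns multi-parametric MRI of paediatric brain tumours — a 4-D
dynamic susceptibility contrast (DSC) series, a pair of diffusion-weighted
volumes, and tumour / normal-appearing-white-matter (NAWM) / brain masks —
into quantitative maps, first-order radiomic features, univariate group
statistics and cross-validated classifiers for two tasks: the three tumour
types (pilocytic astrocytoma, medulloblastoma, ependymoma) and the derived
low/high grade dichotomy (pilocytic astrocytoma is low grade, the other two
high grade). This vignette documents the models, the tunable parameters, the
synthetic cohort that stands in for patient data, and the numerical and
design choices a maintainer would want to know about.

## DSC quantification

**Signal model.** DSC signal is converted to the transverse relaxation
change $\Delta R_2^*(t) = -\ln(S(t)/\bar S_{\mathrm{base}})/TE$, where
$\bar S_{\mathrm{base}}$ is the per-voxel mean over the pre-bolus baseline
window. $\Delta R_2^*$ is treated as proportional to contrast-agent
concentration, the standard high-susceptibility approximation. Voxels with
any non-positive signal inside the brain mask are flagged non-quantifiable
and excluded from the QC mask rather than silently log-transformed.

**Bolus model.** Each voxel's first pass is fitted with the gamma-variate
$C(t) = A (t-t_0)^{\alpha} e^{-(t-t_0)/\beta}$ ($t > t_0$, else 0), by
Levenberg–Marquardt nonlinear least squares (`minpack.lm`). Initialisation:
$t_0$ from the earliest time the curve reaches 10% of its peak (earliest
index on ties, stepped back one sample), and $(\ln A, \alpha, 1/\beta)$ from
the log-linearised regression
$\ln C = \ln A + \alpha \ln(t-t_0) - (t-t_0)/\beta$ over supra-threshold
points, clipped to sane ranges. Bounds keep $A \ge 0$,
$\alpha \in [0.01, 50]$, $\beta \in [0.01, 100]$ s and $t_0$ at or before
the observed peak; tolerances are set near machine precision so noiseless
curves are recovered essentially exactly.

**First-pass window.** The fit uses only the samples up to the first
post-peak point at which the curve falls below 30% of its peak. Recirculation
and contrast leakage distort the tail in ways the gamma-variate cannot
represent; fitting the full series in their presence drives the optimiser
into degenerate corners (tiny $A$, huge $\alpha$), whereas the windowed fit
stays stable and, on leakage-free curves, is exact because a gamma-variate
through any of its own points is the curve itself. The reported fit RMSE is
over the fitted window, and an all-zero or non-finite curve returns the
$A = 0$, `converged = FALSE` convention.

**UCBV.** Uncorrected cerebral blood volume is the analytic integral of the
fitted curve, $A\,\beta^{\alpha+1}\,\Gamma(\alpha+1)$ — not numerical
quadrature — times a single calibration constant mapping arbitrary
concentration–time units onto mL 100 g$^{-1}$ min$^{-1}$. The constant is
chosen per subject so that the NAWM mean of the raw map equals a
configurable literature white-matter value (default 1.5 mL 100 g$^{-1}$
min$^{-1}$). Because maps are subsequently NAWM-normalised, downstream
features are insensitive to this value; it exists so that the absolute
QC ceiling (below) acts on a physiologically meaningful scale.

**Leakage correction.** Blood–brain-barrier disruption lets contrast
extravasate; the T1 effect of accumulating contrast *lowers* the measured
$\Delta R_2^*$. The package uses the standard linear correction: with
$\bar R(t)$ the mean curve over a non-enhancing reference region (brain mask
minus the tumour ROI dilated by one voxel), each voxel is regressed as
$\Delta R_2^*(t) \approx K_1 \bar R(t) - K_2 \int_0^t \bar R(\tau)\,d\tau$,
and $K_2$ (the negated coefficient on the integral regressor) is the
leakage-rate map. Corrected CBV is obtained by adding the estimated leakage
term $K_2 \int_0^t \bar R$ back onto the voxel's curve and refitting the
gamma-variate; the correction is skipped when it is numerically negligible,
so a leakage-free voxel has CCBV exactly equal to its UCBV. We deliberately
refit rather than add the closed-form term $K_2 \iint \bar R$ to UCBV: that
additive form presumes UCBV is the raw curve integral over the acquisition
window, while our UCBV is the analytic integral of a first-pass fit, and
mixing the two conventions overcorrects badly. Refitting keeps the two CBV
definitions consistent and recovers the amplitude-implied CBV of noiseless
leaky voxels. A degenerate (flat) reference curve skips the correction with
a warning and returns CCBV = UCBV.

**QC masking and normalisation.** Voxels are removed from the QC mask when
the gamma-fit RMSE exceeds a noise threshold — by default the 90th
percentile of in-brain RMSE, since no absolute cut-off generalises across
noise levels — or when |UCBV| or |CCBV| exceeds 3.0 mL 100 g$^{-1}$
min$^{-1}$. Masking touches only the mask bookkeeping, never map values, and
is therefore idempotent. CBV maps are then divided by their mean (optionally
median) over the NAWM mask, making the NAWM mean 1 by construction and the
output invariant to any positive rescaling of the input.

## ADC mapping

With two b-values the log-linear least-squares line through
$(b, \ln S)$ is exact: $ADC = \ln(S_{low}/S_{high}) / (b_{high} - b_{low})$,
in mm$^2$/s. Defaults are $b = 0$ and $1000$ s mm$^{-2}$, config-exposed.
Voxels with non-positive signal become missing and are excluded from
features; negative ADC values arising from noise are *retained* — clipping
would bias ROI means upward. Feature tables carry ADC in the conventional
brain scale of $10^{-3}$ mm$^2$/s (recorded in the CSV sidecar schema).

## First-order features

For each map (ADC, UCBV, K2, CCBV) and each region (tumour ROI; whole brain
= brain mask ∩ QC mask, tumour included), four moments over the in-mask
voxel values, plus tumour volume (ROI voxel count × voxel volume / 1000,
cm$^3$): 33 columns in a fixed order. Conventions: SD is the sample (n−1)
estimator; skewness is $m_3/m_2^{3/2}$ and kurtosis the Pearson non-excess
$m_4/m_2^2$ on population central moments — the class profiles' kurtosis
targets of 5–9 only make sense in the non-excess convention (a flag switches
to excess). A constant region has SD 0 and undefined shape moments; regions
with fewer than 8 usable voxels drop the subject with a warning. Whole-brain
statistics include the tumour, matching a plain reading of "whole brain";
excluding it is a one-line mask change.

## Univariate statistics

Per feature, a Shapiro–Wilk test in every group gates the omnibus test:
one-way ANOVA (with Tukey HSD post-hoc) only when all groups are consistent
with normality at $\alpha = 0.05$, otherwise Kruskal–Wallis. After a
Kruskal–Wallis omnibus the post-hoc is a Dunn rank test with tie correction
and Bonferroni over pairs, not Tukey — Tukey's studentised ranges assume
normal residuals, so pairing it with a rank omnibus is incoherent; a
`posthoc = "tukey"` flag forces the Tukey pairing for strict replication of
pipelines that use it. Feature-level significance is Bonferroni-adjusted by
the number of features offered (33 for the full battery; the division is by
features, not features × pairs, with the count exposed). Groups too small or
too degenerate for Shapiro–Wilk fall back to the rank path; a constant
feature returns $p = 1$.

AUC is the rank (Mann–Whitney) statistic with ties counted one half,
oriented by an explicit positive class and reported as-is — values below
0.5 are informative about direction and are never folded in the *reported*
columns. For *ranking* features inside the fold-wise selector, direction is
irrelevant, so the selector scores each feature by the maximum over class
pairs of $\max(AUC, 1-AUC)$.

## Classification protocol

Stratified 3-fold cross-validation: each class is shuffled and dealt
round-robin (fold counts per class differ by at most one; starting offsets
rotate so fold totals balance). Per fold, strictly in order and using
training rows only: optional +100% minority oversampling, dimensionality
reduction, z-scoring on training statistics (for the scale-sensitive SVM,
kNN and neural-network learners; trees are left unscaled), inner
hyperparameter tuning, fitting, and prediction of the untouched test fold.
Pooled test predictions give balanced accuracy (mean per-class recall, %),
macro F1 ("F-statistic"), and macro / per-class precision. Tests verify the
no-leakage structure directly: vandalising the test fold changes
predictions but not the selected features or tuned hyperparameters, and the
input table is bit-identical after a run.

Choices worth recording:

* **PCA arm** — features are standardised on training statistics, components
  accumulate to 95% variance, capped at $N_{min} - 1$ where $N_{min}$ is the
  smallest group size. With oversampling the cap uses the post-oversampling
  group sizes by default (`cap_pre_oversampling` switches), since the
  reduction sees the augmented training set.
* **Univariate arm** — the full gated battery runs inside each training
  fold; Bonferroni survivors are kept, ranked by folded pairwise AUC, with
  a guaranteed minimum of the single best-ranked feature when nothing
  survives.
* **Learners** — AdaBoost is the SAMME multi-class algorithm over depth-1
  `rpart` stumps (implemented in-package; no boosting-over-stumps package is
  a dependency), with the stump count tuned. Random forest tunes `mtry`;
  the RBF-SVM tunes cost; the single-hidden-layer `nnet` tunes width and
  weight decay. Grids are small and fixed; an inner stratified 3-fold CV on
  the training fold picks the grid point with the best macro one-vs-rest
  AUC, capped by `hyperopt_budget`. kNN has no tuned parameters: k is
  round(√n_train), decremented by one when even to avoid vote ties, never
  below 1; prediction is deterministic (remaining ties break by the smaller
  mean neighbour distance, then level order).
* **Oversampling** — replication duplicates every minority training row
  once (+100%); SMOTE synthesises the same number of points by interpolating
  between a minority row and one of its min(5, minority−1) nearest minority
  neighbours, so every synthetic point is a coordinate-wise convex
  combination. The type task targets ependymoma (the smallest class); the
  grade task targets the training fold's minority grade, since ependymoma is
  a subset of "high" there.
* **Perturbation analysis** — every other feature is paired with the
  tumour-ROI mean ADC and the two-feature experiment re-run (no further
  reduction), ranking features by the macro precision they contribute,
  separately for ROI and whole-brain families.

## The synthetic cohort

No patient data are deposited, so the package ships two simulators whose
defaults *are* the study conditions: cohort sizes 22/17/10
(pilocytic astrocytoma / medulloblastoma / ependymoma) and class-conditional
feature distributions given by `default_class_profile()` — per-class mean
and SD for tumour-ROI ADC mean/skewness/kurtosis, whole-brain ADC
mean/skewness/kurtosis, whole-brain corrected CBV mean, and tumour volume,
in the units above.

**Voxel-level generator** (`generate_cohort`). Builds raw volumes: an
ellipsoidal brain, a flattened-ellipsoid tumour sized from the class volume
distribution (truncated below at 0.3 cm$^3$ and above at what the grid can
hold — heavy right tails are clipped on small demonstration grids), and a
contralateral NAWM region disjoint from the dilated ROI. True ADC is drawn
per subject around the class mean with centred skewed voxel deviations
(scaled centred gammas, so the ROI mean is exact by construction and
skewness is approximately matched; kurtosis follows the gamma family rather
than being matched exactly). DSC curves share one bolus shape per subject
($\alpha = 3$, $\beta = 1.5$ s, $t_0 \approx 19$ s with jitter; TR 1.5 s,
60 dynamics, TE 30 ms — temporal settings are config-exposed since
acquisition protocols vary) with voxel-wise log-normal amplitude spread;
whole-brain CBV class structure is induced by solving the background
amplitude for the class's normalised whole-brain target, and tumour voxels
leak with class-dependent $K_2$. Leakage *subtracts* $K_{2}\!\int\!\bar R$
from the measured curve (the T1-dominant sign), where $\bar R$ is the mean
non-leaky curve over the non-tumour brain — exactly the model the corrector
estimates, which is what makes noiseless recovery testable to tight
tolerances. Noise is additive Gaussian on signal (magnitude-MR-like at high
SNR, and invertible at noise 0). Everything derives from one seed;
regeneration is bit-identical.

**Feature-level simulator** (`simulate_feature_table`). Draws the
33-feature table directly: the eight profiled features from their
class-conditional normals (volume truncated at 0.1 cm$^3$ by redraw), the
remaining 25 features as class-independent noise at plausible scales, so
that selection methods must find the informative columns among distractors.
The classification experiments run on this simulator: they probe the
protocol's behaviour given class-structured feature distributions, and a
feature table is what the protocol consumes; re-running the voxel-level
chain for every cohort would only interpose an already-verified (and
numerically near-exact) quantification step at enormous cost.

**What the phantoms do not emulate** — and hence what passing tests do not
show about real data: anatomy and registration error, spatial texture,
between-feature correlations (features are drawn independently, whereas
e.g. UCBV and CCBV are strongly correlated in practice), multi-site field
strength and protocol differences, arterial input variation, motion and
susceptibility artefacts. Results on the phantoms verify the machinery and
the protocol's discriminative behaviour under the stated class profiles,
not clinical performance.

## Problem sizes and verification battery

The test suite exercises the image chain on 16×16×10 grids (hundreds of
in-brain voxels, roughly a second per subject for the per-voxel fits) and
the protocol on 49-subject feature cohorts; these sizes were chosen so the
whole suite stays in the minutes range while every code path runs. The
acceptance battery (`scripts/acceptance.R` and the mirror tests) computes:
noiseless gamma-variate recovery over 100 random curves (sub-0.1% errors),
$K_2$ recovery within 1% with CCBV ≡ UCBV at $K_2 = 0$, ADC inversion at
the $10^{-10}$ level, brute-force oracles for moments and AUC, exact QC
predicate agreement, ~5% type-I error of the gated omnibus under a
simulated null, chance-level balanced accuracy under label permutation
(≈33.3% / ≈50%), and — across 25 simulated cohorts — a univariate-selection
arm that beats both chance (one-sided binomial) and the all-features PCA
arm in the majority of seeds, reproducing the qualitative ordering that
targeted feature selection outperforms variance-based reduction when few
informative features hide among many.

## Known limitations

* The gamma-variate is fitted independently per voxel; no spatial
  regularisation or arterial-input deconvolution (CBF/MTT are out of
  scope).
* $K_2$ is reported in raw regression units; only CBV maps are calibrated
  and NAWM-normalised.
* The two-point ADC cannot separate perfusion and diffusion compartments
  (no IVIM/kurtosis fitting).
* With 49 subjects and 3 folds, cross-validated metrics have large variance;
  single-cohort comparisons between arms should be read accordingly (the
  acceptance battery therefore aggregates over 25 cohorts).
* SMOTE and replication duplicate information in small minority classes;
  oversampling results on simulated cohorts are noisy and can go either
  way, which mirrors their instability at this cohort size.
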