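#' Default class profile: per-type feature means and SDs
#'
#' Target distributions of the discriminating imaging features for the three
#' paediatric tumour types (pilocytic astrocytoma, medulloblastoma,
#' ependymoma). ADC features are in units of 1e-3 mm^2/s, corrected CBV in
#' NAWM-normalised units, tumour volume in cm^3. These defaults drive both
#' the voxel-level phantom generator and the feature-level cohort simulator.
#'
#' @return A data.frame with columns `feature`, `class`, `mean`, `sd`.
#' @export
default_class_profile <- function() {
  pa <- "pilocytic_astrocytoma"; mb <- "medulloblastoma"; ep <- "ependymoma"
  rows <- list(
    c("ADC_ROI_mean",      pa, 1.5, 0.4), c("ADC_ROI_mean",      ep, 1.2, 0.1),
    c("ADC_ROI_mean",      mb, 0.9, 0.2),
    c("ADC_ROI_skewness",  pa, 0.9, 1.0), c("ADC_ROI_skewness",  ep, 2.0, 1.0),
    c("ADC_ROI_skewness",  mb, 1.9, 0.9),
    c("ADC_ROI_kurtosis",  pa, 5.0, 3.0), c("ADC_ROI_kurtosis",  ep, 8.0, 5.0),
    c("ADC_ROI_kurtosis",  mb, 9.0, 5.0),
    c("ADC_WB_mean",       pa, 0.9, 0.2), c("ADC_WB_mean",       ep, 0.7, 0.3),
    c("ADC_WB_mean",       mb, 0.6, 0.2),
    c("ADC_WB_skewness",   pa, 1.2, 0.3), c("ADC_WB_skewness",   ep, 1.5, 0.5),
    c("ADC_WB_skewness",   mb, 1.6, 0.5),
    c("ADC_WB_kurtosis",   pa, 5.0, 1.0), c("ADC_WB_kurtosis",   ep, 6.0, 2.0),
    c("ADC_WB_kurtosis",   mb, 7.0, 2.0),
    c("CCBV_WB_mean",      pa, 1.1, 0.3), c("CCBV_WB_mean",      ep, 1.2, 0.2),
    c("CCBV_WB_mean",      mb, 1.3, 0.2),
    c("tumour_volume_cm3", pa, 2.3, 3.1), c("tumour_volume_cm3", ep, 9.0, 11.2),
    c("tumour_volume_cm3", mb, 3.3, 2.3))
  out <- data.frame(
    feature = vapply(rows, `[`, "", 1L),
    class   = vapply(rows, `[`, "", 2L),
    mean    = as.numeric(vapply(rows, `[`, "", 3L)),
    sd      = as.numeric(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  validate_class_profile(out)
  out
}

validate_class_profile <- function(profile) {
  need <- c("feature", "class", "mean", "sd")
  if (!all(need %in% names(profile)))
    stop("class profile must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(profile$sd)) || any(profile$sd <= 0))
    stop("class profile SDs must all be positive")
  invisible(profile)
}

profile_value <- function(profile, feature, class) {
  row <- profile[profile$feature == feature & profile$class == class, ]
  if (nrow(row) != 1L)
    stop("profile has no unique row for ", feature, " / ", class)
  c(mean = row$mean, sd = row$sd)
}

#' Configuration for a synthetic phantom cohort
#'
#' @param n_per_class Named integer vector of subjects per tumour type.
#'   Defaults to the study cohort sizes: 22 pilocytic astrocytoma,
#'   17 medulloblastoma, 10 ependymoma.
#' @param grid_shape Voxel dimensions of every volume (x, y, z).
#' @param voxel_size_mm Physical voxel edge lengths in mm.
#' @param n_timepoints Number of DSC dynamics.
#' @param tr_s DSC repetition time in seconds (temporal spacing).
#' @param te_s Echo time in seconds.
#' @param b_values_s_per_mm2 Exactly two diffusion weightings, b1 > b0 >= 0.
#' @param noise_sd Additive Gaussian noise SD on the MR signal (signal units;
#'   baseline signal is `s0`).
#' @param s0 Baseline signal level.
#' @param baseline_n Number of pre-bolus timepoints.
#' @param seed RNG seed; a fixed seed gives a bit-identical cohort.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_class = c(pilocytic_astrocytoma = 22,
                                          medulloblastoma = 17,
                                          ependymoma = 10),
                          grid_shape = c(24, 24, 14),
                          voxel_size_mm = c(2.5, 2.5, 2.5),
                          n_timepoints = 60,
                          tr_s = 1.5,
                          te_s = 0.03,
                          b_values_s_per_mm2 = c(0, 1000),
                          noise_sd = 1,
                          s0 = 100,
                          baseline_n = 10,
                          seed = 1) {
  if (is.null(names(n_per_class)))
    names(n_per_class) <- tumour_classes()[seq_along(n_per_class)]
  if (!all(names(n_per_class) %in% tumour_classes()))
    stop("n_per_class names must be among: ",
         paste(tumour_classes(), collapse = ", "))
  if (any(n_per_class < 1)) stop("all class counts must be >= 1")
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop("grid_shape must be three dimensions, each >= 8")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive lengths")
  if (length(b_values_s_per_mm2) != 2L)
    stop("exactly two b-values are required")
  b <- sort(b_values_s_per_mm2)
  if (b[1] < 0 || b[2] <= b[1])
    stop("b-values must satisfy b_high > b_low >= 0")
  if (tr_s <= 0 || te_s <= 0) stop("TR and TE must be positive")
  if (n_timepoints < 10) stop("at least 10 DSC timepoints are required")
  if (baseline_n < 1 || baseline_n >= n_timepoints)
    stop("baseline_n must be in [1, n_timepoints)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (s0 <= 0) stop("s0 must be positive")
  structure(list(n_per_class = n_per_class, grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, n_timepoints = as.integer(n_timepoints),
                 tr_s = tr_s, te_s = te_s, b_values_s_per_mm2 = b,
                 noise_sd = noise_sd, s0 = s0, baseline_n = as.integer(baseline_n),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' DSC signal time course from gamma-variate bolus parameters
#'
#' Forward model for a single voxel: concentration
#' `C(t) = gamma_variate(t, A, alpha, beta, t0)`, optionally reduced by a
#' contrast-leakage term `K2_true` times the running integral of a reference
#' (non-leaky) concentration curve, converted to signal through the
#' susceptibility-contrast relation `S(t) = S0 exp(-TE * C(t))`. Leakage
#' lowers the measured Delta-R2* (the T1-dominant extravasation effect), which
#' is what the Boxerman-style correction later estimates as a positive K2.
#'
#' @inheritParams gamma_variate
#' @param K2_true Leakage rate coefficient (0 for an intact blood-brain
#'   barrier).
#' @param S0 Baseline signal, > 0.
#' @param TE_s Echo time in seconds.
#' @param ref_conc Reference non-leaky concentration curve on the same time
#'   grid; defaults to this voxel's own non-leaky curve.
#' @return Signal time series, same length as `t`.
#' @export
gamma_variate_signal <- function(A, alpha, beta, t0, K2_true = 0, t,
                                 S0 = 100, TE_s = 0.03, ref_conc = NULL) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma-variate shape and scale must be positive")
  if (S0 <= 0) stop("S0 must be positive")
  if (t0 < min(t) || t0 > max(t))
    stop("bolus arrival t0 must lie within the time grid")
  conc <- gamma_variate(t, A, alpha, beta, t0)
  if (K2_true != 0) {
    if (is.null(ref_conc)) ref_conc <- conc
    conc <- conc - K2_true * cumtrapz1(t, ref_conc)
  }
  S0 * exp(-TE_s * conc)
}

#' Diffusion-weighted signal from a true ADC
#'
#' Mono-exponential decay `S = S0 exp(-b * ADC)`.
#'
#' @param adc_true Apparent diffusion coefficient in mm^2/s, >= 0.
#' @param b Diffusion weighting in s/mm^2, >= 0.
#' @param S0 Unweighted signal, > 0.
#' @return Signal (same shape as `adc_true`).
#' @export
diffusion_signal <- function(adc_true, b, S0 = 100) {
  if (b < 0) stop("b-value must be >= 0")
  if (any(S0 <= 0)) stop("S0 must be positive")
  if (any(adc_true < 0)) stop("adc_true must be >= 0")
  S0 * exp(-b * adc_true)
}

ellipsoid_mask <- function(grid_shape, center, semi) {
  x <- seq_len(grid_shape[1]); y <- seq_len(grid_shape[2]); z <- seq_len(grid_shape[3])
  dx2 <- ((x - center[1]) / semi[1])^2
  dy2 <- ((y - center[2]) / semi[2])^2
  dz2 <- ((z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Dilate a binary mask by a Chebyshev radius
#' @keywords internal
dilate_mask <- function(mask, r = 1L) {
  d <- dim(mask)
  out <- mask
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
    out <- out | mask[xs, ys, zs]
  }
  out
}

# skewed zero-mean deviates: scaled, centred gamma with skewness `skew`
skewed_deviates <- function(n, sd, skew) {
  skew <- max(skew, 0.2)
  k <- (2 / skew)^2
  sd * (stats::rgamma(n, shape = k, rate = 1) - k) / sqrt(k)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    bad <- out < lower
    if (!any(bad)) break
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower)
}

#' Generate a synthetic phantom cohort
#'
#' Builds raw per-subject volumes (4-D DSC series, two diffusion-weighted
#' volumes, tumour ROI / NAWM / brain masks) whose quantified feature
#' distributions carry the class structure of [default_class_profile()].
#' Within a subject every voxel shares one bolus shape (alpha, beta, t0) and
#' differs in amplitude, so leakage correction is exactly identified; tumour
#' voxels additionally leak contrast with a class-dependent K2.
#'
#' @param config A [cohort_config()].
#' @param profile Class profile data.frame; defaults to
#'   [default_class_profile()].
#' @return List of subjects; each subject is a list with elements `id`,
#'   `label`, `dsc` (4-D array), `t`, `te_s`, `tr_s`, `baseline_window`,
#'   `b_values`, `dwi_b0`, `dwi_b1`, `roi_mask`, `nawm_mask`, `brain_mask`,
#'   `voxel_size_mm` and `ground_truth` (true ADC map in mm^2/s, true
#'   CBV-proportional amplitude, true K2 map, bolus shape).
#' @export
generate_cohort <- function(config = cohort_config(),
                            profile = default_class_profile()) {
  stopifnot(inherits(config, "cohort_config"))
  validate_class_profile(profile)
  labels <- rep(names(config$n_per_class), times = config$n_per_class)
  with_seed(config$seed, {
    lapply(seq_along(labels), function(i) {
      generate_subject(sprintf("sub-%03d", i), labels[i], config, profile)
    })
  })
}

generate_subject <- function(id, label, config, profile) {
  g <- config$grid_shape
  vox_mm3 <- prod(config$voxel_size_mm)
  center <- (g + 1) / 2
  brain_semi <- (g - 3) / 2
  brain <- ellipsoid_mask(g, center, brain_semi)

  # tumour volume (cm^3) -> flattened ellipsoid (c = 0.55 a) in voxel units
  vol_max_cm3 <- 0.9 * sum(brain) * vox_mm3 / 1000 * 0.25
  vol <- profile_value(profile, "tumour_volume_cm3", label)
  vol_cm3 <- min(rtrunc_norm(1, vol["mean"], vol["sd"], 0.3), vol_max_cm3)
  v_vox <- vol_cm3 * 1000 / vox_mm3
  a <- (v_vox / (4 / 3 * pi * 0.55))^(1 / 3)
  roi_center <- center + c(0.35 * brain_semi[1], 0, 0)
  roi <- ellipsoid_mask(g, roi_center, c(a, a, 0.55 * a))
  if (any(roi & !brain))
    stop("tumour ROI does not fit inside the brain mask; enlarge grid_shape")
  roi <- roi & brain
  if (sum(roi) < 8) stop("tumour ROI too small on this grid; refine voxels")

  nawm <- ellipsoid_mask(g, center - c(0.45 * brain_semi[1], 0, 0),
                         c(0.32 * brain_semi[1], 0.45 * brain_semi[2],
                           0.45 * brain_semi[3]))
  nawm <- nawm & brain & !dilate_mask(roi, 2L)
  if (sum(nawm) < 8) stop("NAWM region too small on this grid")

  nvox <- prod(g)
  in_brain <- which(brain)
  in_roi <- which(roi)
  bg_idx <- setdiff(in_brain, in_roi)

  # --- true ADC (stored in mm^2/s; profile units are 1e-3 mm^2/s) ---
  adc_true <- array(0, g)
  wb <- profile_value(profile, "ADC_WB_mean", label)
  wb_skew <- profile_value(profile, "ADC_WB_skewness", label)
  bg_mean <- rtrunc_norm(1, wb["mean"], wb["sd"], 0.3)
  adc_true[bg_idx] <- pmax(
    bg_mean + skewed_deviates(length(bg_idx), 0.25, max(wb_skew["mean"], 0.3)),
    0.05) * 1e-3
  ro <- profile_value(profile, "ADC_ROI_mean", label)
  ro_skew <- profile_value(profile, "ADC_ROI_skewness", label)
  roi_mean <- rtrunc_norm(1, ro["mean"], ro["sd"], 0.35)
  dev <- skewed_deviates(length(in_roi), 0.25, max(ro_skew["mean"], 0.3))
  dev <- dev - mean(dev)                       # ROI mean is exact by construction
  adc_true[in_roi] <- pmax(roi_mean + dev, 0.05) * 1e-3

  # --- DSC: one bolus shape per subject, voxel-wise amplitudes ---
  alpha <- 3; beta <- 1.5
  t <- (seq_len(config$n_timepoints) - 1) * config$tr_s
  t0 <- config$baseline_n * config$tr_s + 4 + stats::runif(1, -1.5, 1.5)
  shape_curve <- gamma_variate(t, 1, alpha, beta, t0)

  amp <- array(0, g)
  amp_nawm <- 7
  roi_ratio <- max(stats::rnorm(1, 1.5, 0.15), 0.5)
  ccbv_wb <- profile_value(profile, "CCBV_WB_mean", label)
  target <- rtrunc_norm(1, ccbv_wb["mean"], ccbv_wb["sd"], 0.5)
  n_rest <- length(bg_idx) - sum(nawm)
  f_rest <- (target * length(in_brain) - sum(nawm) - length(in_roi) * roi_ratio) /
    n_rest
  f_rest <- min(max(f_rest, 0.3), 3)
  amp[which(nawm)] <- amp_nawm
  amp[setdiff(bg_idx, which(nawm))] <- amp_nawm * f_rest
  amp[in_roi] <- amp_nawm * roi_ratio
  amp[in_brain] <- amp[in_brain] *
    exp(stats::rnorm(length(in_brain), 0, 0.08))   # voxel-wise spread

  k2_true <- array(0, g)
  k2_class <- c(pilocytic_astrocytoma = 0.008, medulloblastoma = 0.03,
                ependymoma = 0.025)[[label]]
  k2_true[in_roi] <- pmax(stats::rnorm(length(in_roi), k2_class,
                                       0.25 * k2_class), 0)

  # non-leaky mean curve over the future reference region (brain minus ROI)
  ref_curve <- mean(amp[bg_idx]) * shape_curve
  ref_int <- cumtrapz1(t, ref_curve)

  nt <- length(t)
  dsc <- array(config$s0, c(g, nt))
  conc <- outer(amp[in_brain], shape_curve) -
    outer(k2_true[in_brain], ref_int)
  sig <- config$s0 * exp(-config$te_s * conc)
  for (j in seq_len(nt)) {
    vol_j <- array(config$s0, g)
    vol_j[in_brain] <- sig[, j]
    dsc[, , , j] <- vol_j
  }
  if (config$noise_sd > 0)
    dsc <- dsc + array(stats::rnorm(length(dsc), 0, config$noise_sd), dim(dsc))

  # --- DWI pair ---
  b <- config$b_values_s_per_mm2
  dwi_b0 <- diffusion_signal(adc_true, b[1], config$s0)
  dwi_b1 <- diffusion_signal(adc_true, b[2], config$s0)
  if (config$noise_sd > 0) {
    dwi_b0 <- dwi_b0 + array(stats::rnorm(nvox, 0, config$noise_sd), g)
    dwi_b1 <- dwi_b1 + array(stats::rnorm(nvox, 0, config$noise_sd), g)
  }

  list(id = id, label = label, dsc = dsc, t = t, te_s = config$te_s,
       tr_s = config$tr_s, baseline_window = seq_len(config$baseline_n),
       b_values = b, dwi_b0 = dwi_b0, dwi_b1 = dwi_b1,
       roi_mask = roi, nawm_mask = nawm, brain_mask = brain,
       voxel_size_mm = config$voxel_size_mm,
       ground_truth = list(adc = adc_true, cbv_amp = amp, k2 = k2_true,
                           shape = c(alpha = alpha, beta = beta, t0 = t0)))
}

#' Simulate a feature table directly from the class profile
#'
#' Draws the subjects-by-features table at the feature level: the eight
#' profiled features come from their class-conditional normal distributions
#' (tumour volume truncated at 0.1 cm^3), the remaining first-order features
#' are class-independent noise with physiologically plausible scales. This is
#' the cohort model used for the classification-protocol experiments, where
#' only the feature distributions matter.
#'
#' @param n_per_class Named vector of subjects per class (defaults to
#'   22/17/10).
#' @param profile Class profile as in [default_class_profile()].
#' @param seed RNG seed.
#' @return A `data.frame` with `subject_id`, `label`, `grade` and the 33
#'   feature columns in canonical order.
#' @export
simulate_feature_table <- function(n_per_class = c(pilocytic_astrocytoma = 22,
                                                   medulloblastoma = 17,
                                                   ependymoma = 10),
                                   profile = default_class_profile(),
                                   seed = 1) {
  validate_class_profile(profile)
  if (is.null(names(n_per_class)))
    names(n_per_class) <- tumour_classes()[seq_along(n_per_class)]
  labels <- rep(names(n_per_class), times = n_per_class)
  n <- length(labels)
  noise_scales <- c(
    ADC_ROI_sd = 0.35, ADC_WB_sd = 0.30,
    UCBV_ROI_mean = 1.5, UCBV_ROI_sd = 0.8, UCBV_ROI_skewness = 1.0,
    UCBV_ROI_kurtosis = 5, UCBV_WB_mean = 1.15, UCBV_WB_sd = 0.6,
    UCBV_WB_skewness = 1.3, UCBV_WB_kurtosis = 6,
    K2_ROI_mean = 0.02, K2_ROI_sd = 0.01, K2_ROI_skewness = 0.5,
    K2_ROI_kurtosis = 4, K2_WB_mean = 0.005, K2_WB_sd = 0.006,
    K2_WB_skewness = 0.8, K2_WB_kurtosis = 4.5,
    CCBV_ROI_mean = 1.4, CCBV_ROI_sd = 0.75, CCBV_ROI_skewness = 1.0,
    CCBV_ROI_kurtosis = 5, CCBV_WB_sd = 0.55, CCBV_WB_skewness = 1.2,
    CCBV_WB_kurtosis = 5.5)
  noise_sds <- c(
    ADC_ROI_sd = 0.08, ADC_WB_sd = 0.05,
    UCBV_ROI_mean = 0.45, UCBV_ROI_sd = 0.2, UCBV_ROI_skewness = 0.5,
    UCBV_ROI_kurtosis = 1.5, UCBV_WB_mean = 0.25, UCBV_WB_sd = 0.15,
    UCBV_WB_skewness = 0.4, UCBV_WB_kurtosis = 1.5,
    K2_ROI_mean = 0.008, K2_ROI_sd = 0.004, K2_ROI_skewness = 0.4,
    K2_ROI_kurtosis = 1, K2_WB_mean = 0.002, K2_WB_sd = 0.002,
    K2_WB_skewness = 0.4, K2_WB_kurtosis = 1,
    CCBV_ROI_mean = 0.4, CCBV_ROI_sd = 0.2, CCBV_ROI_skewness = 0.5,
    CCBV_ROI_kurtosis = 1.5, CCBV_WB_sd = 0.12, CCBV_WB_skewness = 0.4,
    CCBV_WB_kurtosis = 1.5)
  cols <- feature_column_names()
  with_seed(seed, {
    tab <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
    for (cl in unique(labels)) {
      rows <- which(labels == cl)
      for (f in unique(profile$feature)) {
        pv <- profile_value(profile, f, cl)
        tab[rows, f] <- if (f == "tumour_volume_cm3")
          rtrunc_norm(length(rows), pv["mean"], pv["sd"], 0.1)
        else stats::rnorm(length(rows), pv["mean"], pv["sd"])
      }
    }
    for (f in names(noise_scales))
      tab[, f] <- stats::rnorm(n, noise_scales[[f]], noise_sds[[f]])
    out <- data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
                      label = factor(labels, levels = tumour_classes()),
                      stringsAsFactors = FALSE)
    out$grade <- grade_task_labels(out$label)
    cbind(out, as.data.frame(tab))
  })
}

#' Canonical feature column order
#'
#' Four maps (ADC, UCBV, K2, CCBV) x two regions (tumour ROI, whole brain) x
#' four first-order statistics, plus tumour volume: 33 columns.
#'
#' @return Character vector of feature column names.
#' @export
feature_column_names <- function() {
  out <- character(0)
  for (m in c("ADC", "UCBV", "K2", "CCBV"))
    for (r in c("ROI", "WB"))
      for (s in c("mean", "sd", "skewness", "kurtosis"))
        out <- c(out, paste(m, r, s, sep = "_"))
  c(out, "tumour_volume_cm3")
}
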