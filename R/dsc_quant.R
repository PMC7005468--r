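#' Convert a DSC signal series to Delta-R2* concentration
#'
#' Per voxel, \eqn{\Delta R_2^*(t) = -\ln(S(t)/\bar S_{base}) / TE}, where
#' \eqn{\bar S_{base}} is the mean signal over the pre-bolus baseline window.
#' Delta-R2* is taken as proportional to contrast-agent concentration.
#'
#' @param signal 4-D array (x, y, z, t) of DSC signal.
#' @param te_s Echo time in seconds.
#' @param baseline_window Integer indices of pre-bolus timepoints.
#' @param brain_mask Logical 3-D array; voxels outside are left `NA`.
#' @return 4-D array of Delta-R2* (s^-1). Voxels inside the mask with any
#'   non-positive signal are set `NA` (flagged non-quantifiable); their count
#'   is recorded in the `"n_bad_voxels"` attribute.
#' @export
signal_to_delta_r2star <- function(signal, te_s, baseline_window, brain_mask) {
  d <- dim(signal)
  if (length(d) != 4L) stop("'signal' must be a 4-D array")
  if (!length(baseline_window) || any(baseline_window < 1) ||
      any(baseline_window > d[4]))
    stop("invalid baseline window")
  if (!identical(dim(brain_mask), d[1:3]))
    stop("brain_mask shape does not match the series")
  nvox <- prod(d[1:3])
  sig <- matrix(signal, nvox, d[4])[which(brain_mask), , drop = FALSE]
  bad <- rowSums(sig <= 0) > 0
  base <- rowMeans(sig[, baseline_window, drop = FALSE])
  bad <- bad | base <= 0
  conc_in <- matrix(NA_real_, nrow(sig), d[4])
  ok <- !bad
  conc_in[ok, ] <- -log(sig[ok, , drop = FALSE] / base[ok]) / te_s
  out <- array(NA_real_, d)
  flat <- matrix(out, nvox, d[4])
  flat[which(brain_mask), ] <- conc_in
  out <- array(flat, d)
  attr(out, "n_bad_voxels") <- sum(bad)
  out
}

#' Fit a gamma-variate bolus model to one concentration curve
#'
#' Nonlinear least squares over (A, alpha, beta, t0), seeded by the time the
#' curve first reaches 10% of its peak (earliest index on ties) and a
#' log-linearised regression for the shape parameters, refined with
#' Levenberg-Marquardt. The fit is restricted to the first-pass window — from
#' the start of the series until the curve first decays below 30% of its peak
#' after the peak — so that recirculation and contrast-leakage tails (which
#' the gamma-variate cannot represent) do not bias the bolus parameters; the
#' reported RMSE is over that window.
#'
#' @param conc Concentration time series (Delta-R2*, s^-1).
#' @param t Time grid in seconds, same length.
#' @return List of class `gamma_fit`: `A`, `alpha`, `beta`, `t0`, `rmse`,
#'   `converged`. An all-zero (or non-finite) curve returns `A = 0`,
#'   `converged = FALSE`.
#' @export
fit_gamma_variate <- function(conc, t) {
  if (length(conc) != length(t)) stop("'conc' and 't' must have equal length")
  if (length(conc) < 10L) stop("at least 10 samples are required")
  failed <- list(A = 0, alpha = NA_real_, beta = NA_real_, t0 = NA_real_,
                 rmse = if (all(is.finite(conc))) sqrt(mean(conc^2)) else NA_real_,
                 converged = FALSE)
  class(failed) <- "gamma_fit"
  if (any(!is.finite(conc))) return(failed)
  cmax <- max(conc)
  if (cmax <= 0 || max(abs(conc)) < 1e-12) return(failed)
  p <- which.max(conc)
  if (p < 3L) return(failed)

  # first-pass window: drop the post-peak tail once it falls below 30% of peak
  post <- which(seq_along(conc) > p & conc < 0.3 * cmax)
  end <- if (length(post)) max(post[1], min(10L, length(conc)))
         else length(conc)
  conc <- conc[seq_len(end)]
  t <- t[seq_len(end)]

  arrived <- which(conc[seq_len(p)] >= 0.1 * cmax)
  i0 <- arrived[1]
  t0_init <- if (i0 > 1) t[i0 - 1] else t[1]
  alpha0 <- 3; beta0 <- max((t[p] - t0_init) / 3, 0.3)
  use <- which(t > t0_init + 1e-9 & conc > 0.05 * cmax)
  if (length(use) >= 4) {
    dt <- t[use] - t0_init
    fit0 <- try(stats::lm.fit(cbind(1, log(dt), -dt), log(conc[use])), silent = TRUE)
    if (!inherits(fit0, "try-error") && all(is.finite(fit0$coefficients))) {
      a0 <- fit0$coefficients[2]; b0 <- fit0$coefficients[3]
      if (is.finite(a0)) alpha0 <- min(max(a0, 0.3), 20)
      if (is.finite(b0) && b0 > 1e-3) beta0 <- min(max(1 / b0, 0.1), 50)
    }
  }
  A0 <- cmax / max(gamma_variate(t[p], 1, alpha0, beta0, t0_init), 1e-12)

  res_fun <- function(par) gamma_variate(t, par[1], par[2], par[3], par[4]) - conc
  fit <- try(minpack.lm::nls.lm(
    par = c(A0, alpha0, beta0, t0_init),
    lower = c(0, 1e-2, 1e-2, t[1]),
    upper = c(Inf, 50, 100, t[p]),
    fn = res_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                         ptol = 1e-13)), silent = TRUE)
  if (inherits(fit, "try-error")) return(failed)
  par <- fit$par
  rmse <- sqrt(mean(res_fun(par)^2))
  converged <- fit$info %in% 1:3 && par[2] > 0 && par[3] > 0 && par[1] >= 0
  out <- list(A = par[1], alpha = par[2], beta = par[3], t0 = par[4],
              rmse = rmse, converged = converged)
  class(out) <- "gamma_fit"
  out
}

#' Uncorrected CBV from a converged gamma-variate fit
#'
#' The analytic integral of the fitted curve,
#' \eqn{A \beta^{\alpha+1} \Gamma(\alpha+1)}, times a calibration constant
#' taking arbitrary concentration-time units to mL 100 g^-1 min^-1.
#'
#' @param fit A `gamma_fit`.
#' @param calibration Multiplicative calibration constant (default 1 = raw
#'   units).
#' @return Scalar UCBV; `NA` for a non-converged fit (masked downstream).
#' @export
compute_ucbv <- function(fit, calibration = 1) {
  if (!inherits(fit, "gamma_fit")) stop("'fit' must be a gamma_fit")
  if (!isTRUE(fit$converged)) return(NA_real_)
  calibration * gamma_variate_integral(fit$A, fit$alpha, fit$beta)
}

#' Fit the gamma-variate model over a masked 4-D volume
#'
#' @param conc 4-D Delta-R2* array (voxels outside the mask may be `NA`).
#' @param t Time grid in seconds.
#' @param mask Logical 3-D array of voxels to fit.
#' @return List of 3-D arrays `A`, `alpha`, `beta`, `t0`, `rmse`, and logical
#'   `converged`.
#' @export
fit_dsc_volume <- function(conc, t, mask) {
  d <- dim(conc)
  idx <- which(mask)
  flat <- matrix(conc, prod(d[1:3]), d[4])
  empty <- array(NA_real_, d[1:3])
  out <- list(A = empty, alpha = empty, beta = empty, t0 = empty,
              rmse = empty, converged = array(FALSE, d[1:3]))
  for (v in idx) {
    f <- fit_gamma_variate(flat[v, ], t)
    out$A[v] <- f$A; out$alpha[v] <- f$alpha; out$beta[v] <- f$beta
    out$t0[v] <- f$t0; out$rmse[v] <- f$rmse; out$converged[v] <- f$converged
  }
  out
}

#' Vectorised UCBV map from per-voxel fit arrays
#'
#' @param fits Output of [fit_dsc_volume()].
#' @param calibration Multiplicative unit calibration.
#' @return 3-D UCBV array (`NA` where unconverged).
#' @export
ucbv_from_fits <- function(fits, calibration = 1) {
  ok <- fits$converged & is.finite(fits$A)
  out <- array(NA_real_, dim(fits$A))
  out[ok] <- calibration * fits$A[ok] * fits$beta[ok]^(fits$alpha[ok] + 1) *
    gamma(fits$alpha[ok] + 1)
  out
}

#' Boxerman-style contrast-leakage correction
#'
#' Regresses each voxel's Delta-R2* curve on the mean curve of a non-enhancing
#' reference region and its running integral,
#' \eqn{\Delta R_2^*(t) \approx K_1 \bar R(t) - K_2 \int_0^t \bar R(\tau) d\tau},
#' and returns the leakage-rate map K2 together with corrected CBV. CCBV is
#' obtained by adding the estimated leakage term \eqn{K_2 \int \bar R} back
#' onto the voxel's curve and refitting the gamma-variate, so the correction
#' is consistent with the analytic-integral CBV definition: a leakage-free
#' voxel (K2 = 0) has CCBV exactly equal to its UCBV, and a noiselessly
#' simulated leaky voxel recovers its amplitude-implied CBV.
#'
#' @param conc 4-D Delta-R2* array.
#' @param t Time grid in seconds.
#' @param reference_mask Logical 3-D array of non-enhancing voxels (must not
#'   intersect the tumour ROI).
#' @param ucbv UCBV map in the same (raw or calibrated) units as `conc`
#'   integrals; the correction term is added in those units.
#' @param fit_mask Logical 3-D array of voxels whose K2 is estimated
#'   (defaults to all voxels with a complete concentration curve).
#' @return List with 3-D arrays `k2` and `ccbv`, plus the scalar
#'   `double_integral` used in the correction.
#' @export
leakage_correct <- function(conc, t, reference_mask, ucbv, fit_mask = NULL) {
  d <- dim(conc)
  if (!identical(dim(reference_mask), d[1:3]))
    stop("reference_mask shape does not match")
  if (sum(reference_mask) < 1) stop("reference_mask is empty")
  flat <- matrix(conc, prod(d[1:3]), d[4])
  if (is.null(fit_mask))
    fit_mask <- array(stats::complete.cases(flat), d[1:3])
  ref_rows <- flat[which(reference_mask), , drop = FALSE]
  ref_rows <- ref_rows[stats::complete.cases(ref_rows), , drop = FALSE]
  if (!nrow(ref_rows)) stop("reference_mask has no quantifiable voxels")
  rbar <- colMeans(ref_rows)
  rint <- cumtrapz1(t, rbar)
  k2 <- array(0, d[1:3])
  if (stats::sd(rbar) < 1e-10) {
    warning("flat reference curve; leakage correction skipped (CCBV = UCBV)")
    return(list(k2 = k2, ccbv = ucbv, double_integral = 0))
  }
  X <- cbind(rbar, rint)
  XtX <- crossprod(X)
  idx <- which(fit_mask)
  rows <- flat[idx, , drop = FALSE]
  ok <- stats::complete.cases(rows)
  B <- solve(XtX, t(X) %*% t(rows[ok, , drop = FALSE]))   # 2 x nvox
  k2_vals <- numeric(length(idx))
  k2_vals[ok] <- -B[2, ]
  k2[idx] <- k2_vals
  dd <- trapz1(t, rint)
  ccbv <- ucbv
  for (j in seq_along(idx)) {
    if (!ok[j]) next
    v <- idx[j]
    scale_ref <- max(abs(ucbv[v]), 1, na.rm = TRUE)
    if (abs(k2_vals[j]) * dd <= 1e-12 * scale_ref) next  # negligible leak
    corrected <- flat[v, ] + k2_vals[j] * rint
    refit <- fit_gamma_variate(corrected, t)
    ccbv[v] <- if (refit$converged)
      gamma_variate_integral(refit$A, refit$alpha, refit$beta)
    else NA_real_
  }
  list(k2 = k2, ccbv = ccbv, double_integral = dd)
}

#' Apply the quality-control mask to perfusion maps
#'
#' Removes from the QC mask any voxel whose gamma-fit RMSE exceeds the noise
#' threshold or whose absolute CBV (uncorrected or corrected) exceeds the
#' ceiling of 3.0 mL 100 g^-1 min^-1. Map values themselves are untouched;
#' only the mask bookkeeping changes, so the operation is idempotent.
#'
#' @param maps A `perfusion_maps` list (fields `ucbv`, `ccbv`, `qc_mask`).
#' @param rmse_map 3-D array of per-voxel fit RMSE.
#' @param rmse_threshold Scalar noise threshold on RMSE.
#' @param cbv_ceiling Absolute CBV ceiling (default 3.0 mL 100 g^-1 min^-1).
#' @return `maps` with an updated `qc_mask` (and the thresholds recorded).
#' @export
apply_qc_mask <- function(maps, rmse_map, rmse_threshold, cbv_ceiling = 3.0) {
  if (!identical(dim(rmse_map), dim(maps$qc_mask)))
    stop("rmse_map shape does not match maps")
  keep <- maps$qc_mask &
    is.finite(maps$ucbv) & is.finite(maps$ccbv) &
    is.finite(rmse_map) & rmse_map <= rmse_threshold &
    abs(maps$ucbv) <= cbv_ceiling & abs(maps$ccbv) <= cbv_ceiling
  if (!any(keep)) warning("QC mask is empty after thresholding")
  maps$qc_mask <- keep
  maps$rmse_threshold <- rmse_threshold
  maps$cbv_ceiling <- cbv_ceiling
  maps
}

#' Normalise a map to normal-appearing white matter
#'
#' Divides every voxel by the mean (or median) map value over the NAWM mask,
#' so the NAWM mean (median) of the output is 1 by construction.
#'
#' @param map 3-D array.
#' @param nawm_mask Logical 3-D array, non-empty.
#' @param stat `"mean"` (default) or `"median"` reference statistic.
#' @return Normalised map with the reference value in attribute
#'   `"nawm_reference"`.
#' @export
normalise_to_nawm <- function(map, nawm_mask, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!identical(dim(map), dim(nawm_mask)))
    stop("map and nawm_mask shapes differ")
  vals <- map[nawm_mask]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("NAWM mask has no finite map values")
  ref <- if (stat == "mean") mean(vals) else stats::median(vals)
  if (!is.finite(ref) || abs(ref) < 1e-12)
    stop("NAWM reference value is zero or non-finite; cannot normalise")
  out <- map / ref
  attr(out, "nawm_reference") <- ref
  out
}

#' Quantify one subject's DSC series into perfusion maps
#'
#' Full per-subject DSC chain: Delta-R2* conversion, per-voxel gamma-variate
#' fitting, UCBV from the analytic curve integral, Boxerman-style leakage
#' correction (reference region = brain minus the tumour ROI dilated by one
#' voxel), global calibration of CBV units so the NAWM pre-normalisation mean
#' equals `nawm_reference_cbv`, RMSE/CBV-ceiling QC masking, and NAWM
#' normalisation of the CBV maps.
#'
#' @param subject A subject list as produced by [generate_cohort()] (fields
#'   `dsc`, `t`, `te_s`, `baseline_window`, `roi_mask`, `nawm_mask`,
#'   `brain_mask`).
#' @param rmse_quantile Quantile of in-brain fit RMSE used as the noise
#'   threshold (default 0.9).
#' @param cbv_ceiling Absolute CBV ceiling in mL 100 g^-1 min^-1.
#' @param nawm_reference_cbv Literature white-matter CBV (mL 100 g^-1 min^-1)
#'   the calibration maps the NAWM mean onto; downstream NAWM-normalised
#'   features are insensitive to it.
#' @param nawm_stat Reference statistic for normalisation, `"mean"` or
#'   `"median"`.
#' @param normalise Normalise CBV maps to NAWM (default TRUE).
#' @return List of class `perfusion_maps`: `ucbv`, `k2`, `ccbv`, `qc_mask`,
#'   `rmse`, `converged`, `calibration`, `normalised`, `nawm_reference`,
#'   `fit_report` (fraction converged, median RMSE).
#' @export
quantify_subject <- function(subject, rmse_quantile = 0.9, cbv_ceiling = 3.0,
                             nawm_reference_cbv = 1.5,
                             nawm_stat = c("mean", "median"),
                             normalise = TRUE) {
  nawm_stat <- match.arg(nawm_stat)
  conc <- signal_to_delta_r2star(subject$dsc, subject$te_s,
                                 subject$baseline_window, subject$brain_mask)
  fits <- fit_dsc_volume(conc, subject$t, subject$brain_mask)
  ucbv_raw <- ucbv_from_fits(fits)

  ref_mask <- subject$brain_mask & !dilate_mask(subject$roi_mask, 1L)
  lc <- leakage_correct(conc, subject$t, ref_mask, ucbv_raw)

  nawm_vals <- ucbv_raw[subject$nawm_mask]
  nawm_vals <- nawm_vals[is.finite(nawm_vals)]
  if (!length(nawm_vals) || abs(mean(nawm_vals)) < 1e-12)
    stop("cannot calibrate CBV: no finite NAWM UCBV values")
  calibration <- nawm_reference_cbv / mean(nawm_vals)

  maps <- list(ucbv = ucbv_raw * calibration,
               k2 = lc$k2,
               ccbv = lc$ccbv * calibration,
               qc_mask = subject$brain_mask & fits$converged,
               rmse = fits$rmse,
               converged = fits$converged,
               calibration = calibration,
               normalised = FALSE,
               nawm_reference = NA_real_)
  class(maps) <- "perfusion_maps"

  rmse_in <- fits$rmse[subject$brain_mask]
  thr <- stats::quantile(rmse_in[is.finite(rmse_in)], rmse_quantile,
                         names = FALSE)
  maps <- apply_qc_mask(maps, fits$rmse, thr, cbv_ceiling)

  if (normalise) {
    nawm_qc <- subject$nawm_mask & maps$qc_mask
    if (!any(nawm_qc)) nawm_qc <- subject$nawm_mask
    maps$ucbv <- normalise_to_nawm(maps$ucbv, nawm_qc, nawm_stat)
    maps$nawm_reference <- attr(maps$ucbv, "nawm_reference")
    maps$ccbv <- normalise_to_nawm(maps$ccbv, nawm_qc, nawm_stat)
    maps$normalised <- TRUE
  }
  conv_in <- fits$converged[subject$brain_mask]
  maps$fit_report <- list(fraction_converged = mean(conv_in),
                          median_rmse = stats::median(rmse_in, na.rm = TRUE),
                          rmse_threshold = thr,
                          calibration = calibration)
  maps
}
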