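#' First-order histogram features of a map over a region
#'
#' Mean, standard deviation (sample, n-1), skewness \eqn{m_3/m_2^{3/2}} and
#' Pearson (non-excess) kurtosis \eqn{m_4/m_2^2}, with \eqn{m_k} the central
#' sample moments, computed over the voxels of `region_mask` that survive
#' `qc_mask`. A constant region has sd 0 and undefined (NA) skewness and
#' kurtosis.
#'
#' @param map 3-D array (or a plain numeric vector of in-region values).
#' @param region_mask Logical 3-D array (ignored when `map` is a vector).
#' @param qc_mask Optional logical 3-D array of quantifiable voxels.
#' @param min_voxels Minimum usable voxels (default 8); fewer returns all-NA
#'   with a warning.
#' @param excess_kurtosis If TRUE report kurtosis - 3.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
histogram_features <- function(map, region_mask = NULL, qc_mask = NULL,
                               min_voxels = 8L, excess_kurtosis = FALSE) {
  if (is.null(region_mask)) {
    vals <- as.numeric(map)
  } else {
    keep <- region_mask
    if (!is.null(qc_mask)) keep <- keep & qc_mask
    vals <- map[keep]
  }
  vals <- vals[is.finite(vals)]
  out <- c(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
           kurtosis = NA_real_)
  if (length(vals) < min_voxels) {
    warning("region has fewer than ", min_voxels, " usable voxels")
    return(out)
  }
  n <- length(vals)
  mu <- mean(vals)
  dev <- vals - mu
  m2 <- mean(dev^2)
  out["mean"] <- mu
  out["sd"] <- stats::sd(vals)
  if (m2 > .Machine$double.eps * max(1, mu^2)) {
    out["skewness"] <- mean(dev^3) / m2^1.5
    kurt <- mean(dev^4) / m2^2
    out["kurtosis"] <- if (excess_kurtosis) kurt - 3 else kurt
  } else {
    out["sd"] <- 0
  }
  out
}

#' Tumour volume from an ROI mask
#'
#' @param roi_mask Logical 3-D array.
#' @param voxel_size_mm Physical voxel edge lengths in mm (length 3).
#' @return Volume in cm^3 (0, with a warning, for an empty mask).
#' @export
tumour_volume <- function(roi_mask, voxel_size_mm) {
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be three positive lengths")
  n <- sum(roi_mask)
  if (n == 0) warning("empty tumour ROI; volume is 0")
  n * prod(voxel_size_mm) / 1000
}

#' Assemble the subjects-by-features table from quantified maps
#'
#' For each subject: four first-order statistics of the ADC, UCBV, K2 and
#' CCBV maps over the tumour ROI and the whole brain (brain mask intersected
#' with the QC mask, tumour included), plus tumour volume — 33 feature
#' columns in the canonical [feature_column_names()] order, with the
#' tumour-type label and the derived low/high grade. ADC features are
#' reported in 1e-3 mm^2/s (the conventional brain scale).
#'
#' @param subjects List of subjects (see [generate_cohort()]).
#' @param maps_list List of `perfusion_maps`, one per subject.
#' @param adc_list List of ADC volumes in mm^2/s, one per subject.
#' @param min_voxels Minimum usable voxels per region before a subject is
#'   dropped with a warning.
#' @return A `data.frame` with `subject_id`, `label`, `grade` and the 33
#'   features; attribute `"units"` records column units.
#' @export
build_feature_table <- function(subjects, maps_list, adc_list,
                                min_voxels = 8L) {
  stopifnot(length(subjects) == length(maps_list),
            length(subjects) == length(adc_list))
  stat_names <- c("mean", "sd", "skewness", "kurtosis")
  rows <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]; m <- maps_list[[i]]
    adc <- adc_list[[i]] * 1e3            # mm^2/s -> 1e-3 mm^2/s
    vols <- list(ADC = adc, UCBV = m$ucbv, K2 = m$k2, CCBV = m$ccbv)
    qc <- list(ADC = is.finite(adc) & s$brain_mask, UCBV = m$qc_mask,
               K2 = m$qc_mask, CCBV = m$qc_mask)
    feats <- numeric(0)
    for (mp in names(vols)) {
      for (rg in c("ROI", "WB")) {
        mask <- if (rg == "ROI") s$roi_mask else s$brain_mask
        st <- tryCatch(
          histogram_features(vols[[mp]], mask, qc[[mp]], min_voxels),
          warning = function(w) rep(NA_real_, 4))
        names(st) <- paste(mp, rg, stat_names, sep = "_")
        feats <- c(feats, st)
      }
    }
    feats["tumour_volume_cm3"] <- tumour_volume(s$roi_mask, s$voxel_size_mm)
    c(list(subject_id = s$id, label = s$label), as.list(feats))
  })
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  tab <- tab[, c("subject_id", "label", feature_column_names())]
  complete <- stats::complete.cases(tab[, feature_column_names()])
  if (any(!complete)) {
    warning("dropping ", sum(!complete),
            " subject(s) with empty QC-masked regions: ",
            paste(tab$subject_id[!complete], collapse = ", "))
    tab <- tab[complete, , drop = FALSE]
  }
  tab$label <- factor(tab$label, levels = tumour_classes())
  tab$grade <- grade_task_labels(tab$label)
  tab <- tab[, c("subject_id", "label", "grade", feature_column_names())]
  rownames(tab) <- NULL
  attr(tab, "units") <- c(ADC = "1e-3 mm^2/s", UCBV = "NAWM-normalised",
                          CCBV = "NAWM-normalised", K2 = "raw leakage rate",
                          tumour_volume_cm3 = "cm^3")
  tab
}
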