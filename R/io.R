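# NIfTI, manifest, config and report IO, plus the end-to-end pipeline driver.

manifest_columns <- function() {
  c("subject_id", "label", "dsc", "dwi_b0", "dwi_b1", "roi_mask",
    "nawm_mask", "brain_mask", "b_low", "b_high", "tr_s", "te_s",
    "vox_x_mm", "vox_y_mm", "vox_z_mm", "baseline_n")
}

write_nifti_map <- function(arr, path, voxel_size_mm, descrip = NULL) {
  img <- RNifti::asNifti(arr + 0)          # logical -> numeric
  RNifti::pixdim(img) <- voxel_size_mm
  if (!is.null(descrip)) img$descrip <- substr(descrip, 1, 79)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a synthetic cohort to NIfTI volumes plus a CSV manifest
#'
#' @param subjects List of subjects from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Path of the written `manifest.csv`, invisibly.
#' @export
write_cohort <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(subjects, function(s) {
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    paths <- c(dsc = "dsc.nii.gz", dwi_b0 = "dwi_b0.nii.gz",
               dwi_b1 = "dwi_b1.nii.gz", roi_mask = "roi_mask.nii.gz",
               nawm_mask = "nawm_mask.nii.gz", brain_mask = "brain_mask.nii.gz")
    write_nifti_map(s$dsc, file.path(sdir, paths["dsc"]), s$voxel_size_mm,
                    "DSC signal, arbitrary units")
    write_nifti_map(s$dwi_b0, file.path(sdir, paths["dwi_b0"]),
                    s$voxel_size_mm, sprintf("DWI b=%g s/mm^2", s$b_values[1]))
    write_nifti_map(s$dwi_b1, file.path(sdir, paths["dwi_b1"]),
                    s$voxel_size_mm, sprintf("DWI b=%g s/mm^2", s$b_values[2]))
    for (m in c("roi_mask", "nawm_mask", "brain_mask"))
      write_nifti_map(s[[m]], file.path(sdir, paths[m]), s$voxel_size_mm,
                      "binary mask")
    data.frame(subject_id = s$id, label = as.character(s$label),
               dsc = file.path(s$id, paths["dsc"]),
               dwi_b0 = file.path(s$id, paths["dwi_b0"]),
               dwi_b1 = file.path(s$id, paths["dwi_b1"]),
               roi_mask = file.path(s$id, paths["roi_mask"]),
               nawm_mask = file.path(s$id, paths["nawm_mask"]),
               brain_mask = file.path(s$id, paths["brain_mask"]),
               b_low = s$b_values[1], b_high = s$b_values[2],
               tr_s = s$tr_s, te_s = s$te_s,
               vox_x_mm = s$voxel_size_mm[1], vox_y_mm = s$voxel_size_mm[2],
               vox_z_mm = s$voxel_size_mm[3],
               baseline_n = length(s$baseline_window),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' @param path Path to a `manifest.csv` (file paths inside are resolved
#'   relative to its directory).
#' @return Validated manifest data.frame of class `cohort_manifest`, with the
#'   base directory in attribute `"dir"`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns(), names(man))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  dup <- man$subject_id[duplicated(man$subject_id)]
  if (length(dup))
    stop("duplicated subject id(s): ", paste(unique(dup), collapse = ", "))
  bad_lab <- setdiff(unique(man$label), tumour_classes())
  if (length(bad_lab))
    stop("unknown label(s) in manifest: ", paste(bad_lab, collapse = ", "))
  if (any(man$b_high <= man$b_low | man$b_low < 0))
    stop("manifest b-values must satisfy b_high > b_low >= 0")
  if (any(man$tr_s <= 0) || any(man$te_s <= 0))
    stop("manifest TR and TE must be positive")
  base <- dirname(normalizePath(path))
  file_cols <- c("dsc", "dwi_b0", "dwi_b1", "roi_mask", "nawm_mask",
                 "brain_mask")
  for (col in file_cols) {
    full <- file.path(base, man[[col]])
    gone <- !file.exists(full)
    if (any(gone))
      stop("missing file(s) for column '", col, "': ",
           paste(man[[col]][gone], collapse = ", "))
  }
  structure(man, dir = base, class = c("cohort_manifest", "data.frame"))
}

#' Read one subject's volumes from a loaded manifest
#'
#' @param manifest A [load_manifest()] result.
#' @param i Row index.
#' @return Subject list in the same layout as [generate_cohort()] output
#'   (without ground truth).
#' @export
read_subject <- function(manifest, i) {
  base <- attr(manifest, "dir")
  row <- manifest[i, ]
  rd <- function(col) {
    as.array(RNifti::readNifti(file.path(base, row[[col]])))
  }
  dsc <- rd("dsc")
  list(id = row$subject_id, label = row$label, dsc = dsc,
       t = (seq_len(dim(dsc)[4]) - 1) * row$tr_s,
       te_s = row$te_s, tr_s = row$tr_s,
       baseline_window = seq_len(row$baseline_n),
       b_values = c(row$b_low, row$b_high),
       dwi_b0 = rd("dwi_b0"), dwi_b1 = rd("dwi_b1"),
       roi_mask = rd("roi_mask") > 0.5,
       nawm_mask = rd("nawm_mask") > 0.5,
       brain_mask = rd("brain_mask") > 0.5,
       voxel_size_mm = c(row$vox_x_mm, row$vox_y_mm, row$vox_z_mm))
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [cohort_config()].
#' @return `read_cohort_config` returns a validated [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$n_per_class)) vals$n_per_class <- unlist(vals$n_per_class)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  yaml::write_yaml(lapply(unclass(config), function(v)
    if (is.null(names(v))) unname(v) else as.list(v)), path)
  invisible(path)
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 2^31)
}

#' Quantify every subject of a cohort
#'
#' Runs the DSC chain ([quantify_subject()]) and ADC mapping
#' ([compute_adc()]) for each subject.
#'
#' @param subjects List of subjects.
#' @param ... Passed to [quantify_subject()].
#' @return List with `maps` (perfusion maps per subject) and `adc` (ADC
#'   volumes, mm^2/s).
#' @export
quantify_cohort <- function(subjects, ...) {
  maps <- lapply(subjects, quantify_subject, ...)
  adc <- lapply(subjects, function(s)
    compute_adc(s$dwi_b0, s$dwi_b1, s$b_values[1], s$b_values[2],
                s$brain_mask))
  list(maps = maps, adc = adc)
}

#' Write quantified maps and a fit-quality report for one subject
#'
#' @param subject Subject list.
#' @param maps `perfusion_maps` for that subject.
#' @param adc ADC volume in mm^2/s.
#' @param dir Output directory.
#' @return The subject's output directory, invisibly.
#' @export
write_subject_maps <- function(subject, maps, adc, dir) {
  sdir <- file.path(dir, subject$id)
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  vx <- subject$voxel_size_mm
  write_nifti_map(maps$ucbv, file.path(sdir, "ucbv.nii.gz"), vx,
                  "UCBV, NAWM-normalised")
  write_nifti_map(maps$ccbv, file.path(sdir, "ccbv.nii.gz"), vx,
                  "CCBV, NAWM-normalised")
  write_nifti_map(maps$k2, file.path(sdir, "k2.nii.gz"), vx,
                  "K2 leakage rate, raw units")
  write_nifti_map(maps$qc_mask, file.path(sdir, "qc_mask.nii.gz"), vx,
                  "QC mask")
  write_nifti_map(adc, file.path(sdir, "adc.nii.gz"), vx, "ADC, mm^2/s")
  jsonlite::write_json(maps$fit_report,
                       file.path(sdir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(sdir)
}

#' Write the feature table as CSV with a JSON schema sidecar
#'
#' @param table Feature table.
#' @param path CSV path (the sidecar gets extension `.schema.json`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  schema <- list(
    columns = names(table),
    units = as.list(attr(table, "units") %||%
                      c(ADC = "1e-3 mm^2/s", UCBV = "NAWM-normalised",
                        CCBV = "NAWM-normalised", K2 = "raw leakage rate",
                        tumour_volume_cm3 = "cm^3")),
    conventions = list(sd = "sample (n-1)",
                       skewness = "m3 / m2^1.5",
                       kurtosis = "Pearson m4 / m2^2 (non-excess)",
                       grade = "low = pilocytic astrocytoma; high = others"))
  jsonlite::write_json(schema, sub("\\.csv$", ".schema.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @param path CSV path written by `write_feature_table`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$label <- factor(tab$label, levels = tumour_classes())
  tab$grade <- factor(tab$grade, levels = c("low", "high"))
  tab
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate, quantify, extract features, run the univariate battery for both
#' tasks, and fit the default classification arms (fold-wise univariate
#' selection and all-features PCA, AdaBoost learner) for both the tumour-type
#' and grade tasks. All artefacts are written under `out_dir` and carry the
#' configuration fingerprint and seed.
#'
#' @param config A [cohort_config()]; keep the grid small (the default here
#'   is a reduced demonstration cohort) — per-voxel fitting dominates the
#'   run time.
#' @param out_dir Output directory.
#' @param arms Optional list of [experiment_config()]s to run instead of the
#'   defaults.
#' @return List with `feature_table`, `univariate` (per task), `reports`
#'   (per arm), invisibly.
#' @export
run_full_pipeline <- function(config = cohort_config(
                                n_per_class = c(pilocytic_astrocytoma = 4,
                                                medulloblastoma = 3,
                                                ependymoma = 3),
                                grid_shape = c(16, 16, 10)),
                              out_dir = tempfile("pedmri_run"),
                              arms = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config_fingerprint = config_fingerprint(config))

  subjects <- generate_cohort(config)
  q <- quantify_cohort(subjects)
  for (i in seq_along(subjects))
    write_subject_maps(subjects[[i]], q$maps[[i]], q$adc[[i]],
                       file.path(out_dir, "maps"))
  tab <- build_feature_table(subjects, q$maps, q$adc)
  write_feature_table(tab, file.path(out_dir, "features.csv"))

  univ <- list()
  for (task in c("type", "grade")) {
    univ[[task]] <- run_univariate_battery(tab, task)
    utils::write.csv(univ[[task]],
                     file.path(out_dir, sprintf("univariate_%s.csv", task)),
                     row.names = FALSE)
  }

  if (is.null(arms)) {
    arms <- list(
      type_univariate = experiment_config("type", "univariate_all",
                                          classifier = "adaboost",
                                          seed = config$seed),
      type_pca = experiment_config("type", "all", reduction = "pca",
                                   classifier = "adaboost",
                                   seed = config$seed),
      grade_univariate = experiment_config("grade", "univariate_all",
                                           classifier = "adaboost",
                                           seed = config$seed))
  }
  reports <- lapply(arms, function(a) train_and_evaluate(tab, a))
  summaries <- lapply(reports, function(r)
    list(task = r$config$task, feature_set = r$config$feature_set,
         reduction = r$config$reduction, classifier = r$config$classifier,
         oversampling = r$config$oversampling,
         bar_pct = r$bar, f_stat = r$f_stat,
         macro_precision_pct = r$macro_precision,
         per_class = r$per_class, meta = meta))
  jsonlite::write_json(summaries, file.path(out_dir, "cv_reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(feature_table = tab, univariate = univ, reports = reports,
                 out_dir = out_dir))
}
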