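#' Score a per-lesion feature table
#'
#' The feature-table entry point: takes per-lesion medians/percentiles
#' (columns `lesion_id`, `fa_median`, `cl_median`, `rcbv_max`, optionally
#' `md_median`, `md_min`, `cp_median`, `cs_median`, `reference_label`,
#' `reference_source`), computes the predictive probability and TP/PsP call
#' per lesion, and — when reference labels are present — the concordance
#' summary. Optionally merges modified-RANO calls from a measurement table.
#'
#' @param features `data.frame` in the schema above, or a CSV path.
#' @param model A [prediction_model()].
#' @param rano Optional RANO measurement table (`data.frame` or CSV path,
#'   see [rano_from_table()]); its labels fill missing `reference_label`
#'   entries with source `"modified_RANO"`.
#' @return Object of class `gliopred_report`: `calls` data.frame (features +
#'   `pp`, `pp_percent`, `predicted_label`, `reference_label`,
#'   `reference_source`, `concordant`), `concordance` list (or `NULL` when
#'   no references), and the `model`.
#' @examples
#' rep <- run_from_features(table2_features())
#' rep$concordance$rate
#' @export
run_from_features <- function(features, model = prediction_model(),
                              rano = NULL) {
  if (is.character(features)) {
    if (!file.exists(features))
      stop_gliopred(paste0("feature table not found: ", features),
                    "gliopred_input_error")
    features <- utils::read.csv(features, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(features) || nrow(features) == 0L)
    stop_gliopred("feature table is empty", "gliopred_input_error")
  need <- c("lesion_id", "fa_median", "cl_median", "rcbv_max")
  miss <- setdiff(need, names(features))
  if (length(miss) > 0L)
    stop_gliopred(paste0("feature table is missing column(s): ",
                         paste(miss, collapse = ", ")),
                  "gliopred_input_error")
  for (col in c("fa_median", "cl_median", "rcbv_max")) {
    bad <- which(!is.finite(features[[col]]))
    if (length(bad) > 0L)
      stop_gliopred(sprintf("row %d, column '%s': value must be finite",
                            bad[1L], col), "gliopred_input_error")
  }

  calls <- features
  if (!"reference_label" %in% names(calls))
    calls$reference_label <- NA_character_
  if (!"reference_source" %in% names(calls))
    calls$reference_source <- ifelse(is.na(calls$reference_label),
                                     "none", "unspecified")
  if (!is.null(rano)) {
    rano_calls <- rano_from_table(rano)
    m <- match(as.character(calls$lesion_id),
               as.character(rano_calls$lesion_id))
    fill <- is.na(calls$reference_label) & !is.na(m) &
      rano_calls$label[m] %in% c("TP", "PsP")
    calls$reference_label[fill] <- rano_calls$label[m[fill]]
    calls$reference_source[fill] <- "modified_RANO"
  }

  calls$pp <- compute_pp(calls$fa_median, calls$cl_median, calls$rcbv_max,
                         model = model)
  calls$pp_percent <- format_pp_percent(calls$pp)
  calls$predicted_label <- classify_response(calls$pp, model = model)
  has_ref <- !is.na(calls$reference_label) &
    calls$reference_label %in% c("TP", "PsP")
  calls$concordant <- ifelse(has_ref,
                             calls$predicted_label == calls$reference_label,
                             NA)
  conc <- if (any(has_ref))
    concordance(calls$predicted_label[has_ref],
                calls$reference_label[has_ref])
  else NULL

  structure(list(calls = calls, concordance = conc, model = model),
            class = "gliopred_report")
}

#' @export
print.gliopred_report <- function(x, ...) {
  cat("Multiparametric MRI response assessment\n")
  show <- x$calls[, intersect(c("lesion_id", "fa_median", "cl_median",
                                "rcbv_max", "pp_percent", "predicted_label",
                                "reference_label"), names(x$calls))]
  print(show, row.names = FALSE)
  if (!is.null(x$concordance))
    cat(sprintf("Concordance with reference standard: %d/%d (%.0f%%)\n",
                x$concordance$n_concordant, x$concordance$n_total,
                100 * x$concordance$rate))
  else
    cat("Concordance: undefined (no reference labels)\n")
  invisible(x)
}

#' Run the full imaging pipeline on a study
#'
#' Volume entry point: executes tensor fitting and scalar maps, DSC
#' conversion, bolus detection, gamma-variate characterization, leakage
#' correction and rCBV normalization, reslicing onto the post-contrast T1
#' grid, enhancing-lesion segmentation, feature extraction, and finally the
#' predictive-probability call. Accepts an in-memory study (a
#' [generate_phantom()] result or a [read_study()] result).
#'
#' @param study Study object: components `dwi`, `protocol`, `dsc`,
#'   `pre_t1`, `post_t1`, `brain_mask`, `reference_mask`, `affine`, and
#'   optionally per-map affines (`map_affines`) when the maps are not on
#'   the T1 grid.
#' @param model A [prediction_model()].
#' @param k_sd Segmentation threshold (SD units). Default 3.
#' @param min_component_voxels Minimum enhancing-component size. Default 10.
#' @param integration Integrate the leakage-corrected raw curve
#'   (`"raw"`, default) or the fitted gamma-variate (`"gamma"`).
#' @param provisional_baseline Frames assumed pre-bolus for the initial
#'   conversion. Default `1:5`.
#' @param lesion_id Identifier for the report row.
#' @return A `gliopred_report` whose `maps` element carries the derived
#'   volumes (scalar maps, rCBV, K2, lesion mask) and whose `calls` row is
#'   the extracted feature vector plus PP and label.
#' @export
run_from_volumes <- function(study, model = prediction_model(), k_sd = 3,
                             min_component_voxels = 10L,
                             integration = c("raw", "gamma"),
                             provisional_baseline = 1:5,
                             lesion_id = "lesion") {
  integration <- match.arg(integration)
  for (nm in c("dwi", "protocol", "dsc", "pre_t1", "post_t1", "brain_mask"))
    if (is.null(study[[nm]]))
      stop_gliopred(paste0("study is missing component '", nm, "'"),
                    "gliopred_input_error")
  if (length(dim(study$dwi)) != 4L)
    stop_gliopred("DWI input must be 4D (is the DWI role pointing at a 3D file?)",
                  "gliopred_modality_error")
  if (!inherits(study$dsc, "perfusion_series"))
    stop_gliopred("DSC input must be a perfusion_series (4D + TE/TR sidecar)",
                  "gliopred_modality_error")
  grid <- dim(study$post_t1)

  # --- diffusion branch ---
  field <- fit_tensor(study$dwi, study$protocol, mask = study$brain_mask)
  maps <- scalar_maps(field)

  # --- perfusion branch ---
  prov <- to_concentration(study$dsc, mask = study$brain_mask,
                           baseline = provisional_baseline)
  bol <- detect_bolus(prov, min_baseline = length(provisional_baseline))
  conc <- to_concentration(study$dsc, mask = study$brain_mask,
                           baseline = bol$baseline)
  nonenh <- study$brain_mask
  ref_curve <- colMeans(conc$delta_r2[conc$valid, , drop = FALSE])
  corr <- leakage_correct(conc, ref_curve)
  window <- bol$arrival:length(conc$time_s)
  gv <- tryCatch(fit_gamma_variate(conc$time_s, ref_curve, window = window),
                 error = function(e) NULL)
  if (integration == "gamma" && !is.null(gv) && gv$converged) {
    # scale per-voxel CBV by the ratio of each corrected curve to the
    # reference, using the analytic integral of the fitted first pass
    k1 <- leakage_correct(conc, gv$fitted)$k1
    cbv_v <- k1 * gamma_variate_integral(gv$K, gv$alpha, gv$beta)
    cbv_v[!is.finite(cbv_v) | cbv_v < 0] <- 0
  } else {
    cbv_v <- compute_cbv(corr$corrected, window = window)$cbv
  }
  cbv <- array(0, conc$dims)
  cbv[conc$vox] <- ifelse(is.finite(cbv_v), cbv_v, 0)
  k2_map <- array(0, conc$dims)
  k2_map[conc$vox] <- ifelse(is.finite(corr$k2), corr$k2, 0)
  if (is.null(study$reference_mask) || !any(study$reference_mask))
    stop_gliopred("a contralateral white-matter reference mask is required",
                  "gliopred_normalization_error")
  rcbv <- array(normalize_rcbv(as.numeric(cbv),
                               as.logical(study$reference_mask)), grid)

  # --- reslicing onto the post-contrast T1 grid ---
  res <- function(m, src_affine) {
    if (is.null(src_affine) ||
        (identical(dim(m), grid) &&
         max(abs(src_affine - study$affine)) < 1e-5)) return(m)
    reslice_to_reference(m, src_affine, grid, study$affine)$data
  }
  ma <- study$map_affines
  derived <- list(md = res(maps$md, ma$dwi), fa = res(maps$fa, ma$dwi),
                  cl = res(maps$cl, ma$dwi), cp = res(maps$cp, ma$dwi),
                  cs = res(maps$cs, ma$dwi), rcbv = res(rcbv, ma$dsc))

  # --- lesion segmentation and features ---
  seg <- segment_enhancing(study$post_t1, study$pre_t1, study$brain_mask,
                           k_sd = k_sd,
                           min_component_voxels = min_component_voxels,
                           voxel_mm = study$voxel_mm)
  features <- extract_features(seg, derived, lesion_id = lesion_id)

  report <- run_from_features(features, model = model)
  report$maps <- c(derived, list(k2 = k2_map, lesion_mask = seg$mask))
  report$segmentation <- seg
  report$bolus <- bol
  report$gamma_fit <- gv
  report
}

#' Write a response report to CSV and JSON
#'
#' Serializes the per-lesion calls as CSV and the full report (calls,
#' concordance summary, model coefficients, provenance) as JSON.
#'
#' @param report A `gliopred_report`.
#' @param path Output path prefix; writes `<path>.csv` and `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "gliopred_report"))
  csv <- paste0(path, ".csv")
  json <- paste0(path, ".json")
  utils::write.csv(report$calls, csv, row.names = FALSE)
  payload <- list(
    calls = report$calls,
    concordance = report$concordance,
    model = unclass(report$model),
    software = as.character(utils::packageVersion("gliopred")),
    fixture_checksums = as.list(fixture_checksums()))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
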