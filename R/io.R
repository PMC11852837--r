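# File-based study assembly: NIfTI volumes, FSL-style bval/bvec tables and
# JSON sidecars, via RNifti.

#' Read FSL-style b-value / b-vector tables
#'
#' One whitespace-separated row of b-values and three rows of gradient
#' components, one column per volume.
#'
#' @param bval_path,bvec_path Paths to the two text files.
#' @return A [diffusion_protocol()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  diffusion_protocol(bvals, bvecs)
}

#' Write a 3D/4D array as NIfTI
#'
#' @param data Numeric array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param affine 4x4 voxel-to-world matrix.
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(data, path, affine = diag(4)) {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array with its affine
#'
#' @param path NIfTI file path.
#' @return List with `data` (array) and `affine` (4x4 matrix).
#' @export
read_nifti_map <- function(path) {
  if (!file.exists(path))
    stop_gliopred(paste0("volume not found: ", path), "gliopred_input_error")
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL)
  list(data = array(as.numeric(img), dim(img)), affine = unclass(aff))
}

#' Assemble a study from files on disk
#'
#' Reads the volumes and sidecars the imaging pipeline needs: 4D DWI with
#' bval/bvec tables, 4D DSC with a JSON sidecar carrying `te_ms` and
#' `tr_ms`, pre- and post-contrast T1, and brain / contralateral-reference
#' masks. Every volume is checked for the expected dimensionality before it
#' is accepted in its role.
#'
#' @param dwi,bval,bvec DWI volume and gradient-table paths.
#' @param dsc,dsc_sidecar DSC volume and JSON sidecar paths.
#' @param pre_t1,post_t1 T1 volume paths.
#' @param brain_mask,reference_mask Mask volume paths.
#' @return A study list consumable by [run_from_volumes()].
#' @export
read_study <- function(dwi, bval, bvec, dsc, dsc_sidecar, pre_t1, post_t1,
                       brain_mask, reference_mask) {
  dwi_img <- read_nifti_map(dwi)
  if (length(dim(dwi_img$data)) != 4L)
    stop_gliopred("DWI role requires a 4D volume", "gliopred_modality_error")
  protocol <- read_bval_bvec(bval, bvec)
  if (dim(dwi_img$data)[4L] != length(protocol$bvals))
    stop_gliopred("DWI volume count does not match the gradient table",
                  "gliopred_modality_error")

  dsc_img <- read_nifti_map(dsc)
  if (length(dim(dsc_img$data)) != 4L)
    stop_gliopred("DSC role requires a 4D volume", "gliopred_modality_error")
  side <- jsonlite::read_json(dsc_sidecar, simplifyVector = TRUE)
  if (is.null(side$te_ms) || is.null(side$tr_ms))
    stop_gliopred("DSC sidecar must provide 'te_ms' and 'tr_ms'",
                  "gliopred_modality_error")

  pre <- read_nifti_map(pre_t1)
  post <- read_nifti_map(post_t1)
  for (v in list(pre, post))
    if (length(dim(v$data)) != 3L)
      stop_gliopred("T1 roles require 3D volumes", "gliopred_modality_error")
  bm <- read_nifti_map(brain_mask)
  rm_ <- read_nifti_map(reference_mask)

  list(dwi = dwi_img$data, protocol = protocol,
       dsc = perfusion_series(dsc_img$data, te_ms = side$te_ms,
                              tr_ms = side$tr_ms),
       pre_t1 = pre$data, post_t1 = post$data,
       brain_mask = array(bm$data > 0.5, dim(bm$data)),
       reference_mask = array(rm_$data > 0.5, dim(rm_$data)),
       affine = post$affine,
       map_affines = list(dwi = dwi_img$affine, dsc = dsc_img$affine),
       voxel_mm = sqrt(colSums(post$affine[1:3, 1:3]^2)))
}

#' Write a phantom study to disk
#'
#' Serializes a [generate_phantom()] result in the on-disk layout
#' [read_study()] expects (NIfTI volumes, bval/bvec tables, JSON sidecars),
#' plus a truth sidecar with the planted features and label.
#'
#' @param phantom A `gliopred_phantom`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "gliopred_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  aff <- phantom$affine
  write_nifti_map(phantom$dwi, p("dwi.nii.gz"), aff)
  write_nifti_map(phantom$dsc$signal, p("dsc.nii.gz"), aff)
  write_nifti_map(phantom$pre_t1, p("pre_t1.nii.gz"), aff)
  write_nifti_map(phantom$post_t1, p("post_t1.nii.gz"), aff)
  write_nifti_map(phantom$brain_mask + 0, p("brain_mask.nii.gz"), aff)
  write_nifti_map(phantom$reference_mask + 0, p("reference_mask.nii.gz"), aff)
  writeLines(paste(phantom$protocol$bvals, collapse = " "), p("dwi.bval"))
  utils::write.table(phantom$protocol$bvecs, p("dwi.bvec"),
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(te_ms = phantom$dsc$te_ms,
                            tr_ms = phantom$dsc$tr_ms),
                       p("dsc.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(class = phantom$truth$label,
                            seed = phantom$spec$seed,
                            features = phantom$truth$features,
                            pp = phantom$truth$pp),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(dwi = p("dwi.nii.gz"), dsc = p("dsc.nii.gz"),
              pre_t1 = p("pre_t1.nii.gz"), post_t1 = p("post_t1.nii.gz"),
              brain_mask = p("brain_mask.nii.gz"),
              reference_mask = p("reference_mask.nii.gz"),
              bval = p("dwi.bval"), bvec = p("dwi.bvec"),
              sidecar = p("dsc.json"), truth = p("truth.json")))
}
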