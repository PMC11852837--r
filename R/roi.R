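#' Reslice a map onto a reference voxel grid
#'
#' Resamples a 3D map onto the grid of a reference image (typically the
#' post-contrast T1) through the composed voxel-to-world affines, with
#' trilinear interpolation. No registration is estimated: alignment is taken
#' entirely from the stored affines, so inputs must already be co-registered
#' in world space. Reference voxels that map outside the source field of
#' view receive `fill` and are reported in the output mask.
#'
#' Affines follow the NIfTI convention: world = A %*% c(i, j, k, 1) with
#' 0-based voxel indices.
#'
#' @param img 3D numeric array to resample.
#' @param affine 4x4 voxel-to-world affine of `img`.
#' @param ref_dim Integer length-3 dimensions of the reference grid.
#' @param ref_affine 4x4 voxel-to-world affine of the reference grid.
#' @param fill Value for out-of-field voxels. Default `NA`.
#' @return List with `data` (resampled array on the reference grid) and
#'   `in_field` (logical array, FALSE where `fill` was used).
#' @export
reslice_to_reference <- function(img, affine, ref_dim, ref_affine,
                                 fill = NA_real_) {
  if (length(dim(img)) != 3L)
    stop_gliopred("'img' must be a 3D array", "gliopred_header_error")
  for (A in list(affine, ref_affine)) {
    if (!is.matrix(A) || !identical(dim(A), c(4L, 4L)) || anyNA(A) ||
        abs(det(A)) < 1e-12)
      stop_gliopred("a valid invertible 4x4 affine is required",
                    "gliopred_header_error")
  }
  ref_dim <- as.integer(ref_dim)

  if (identical(dim(img), ref_dim) &&
      max(abs(affine - ref_affine)) < 1e-5) {
    return(list(data = img, in_field = array(TRUE, ref_dim)))
  }

  # reference voxel (0-based) -> world -> source voxel (0-based)
  M <- solve(affine) %*% ref_affine
  grid <- as.matrix(expand.grid(i = seq_len(ref_dim[1L]) - 1L,
                                j = seq_len(ref_dim[2L]) - 1L,
                                k = seq_len(ref_dim[3L]) - 1L))
  src <- t(M %*% rbind(t(grid), 1))[, 1:3, drop = FALSE]

  d <- dim(img)
  x <- src[, 1L]; y <- src[, 2L]; z <- src[, 3L]
  inside <- x >= 0 & x <= d[1L] - 1L & y >= 0 & y <= d[2L] - 1L &
    z >= 0 & z <= d[3L] - 1L
  if (!any(inside))
    stop_gliopred("reference grid has no overlap with the source field of view",
                  "gliopred_geometry_error")

  out <- rep(fill, nrow(src))
  xi <- pmin(floor(x[inside]), d[1L] - 2L); xf <- x[inside] - xi
  yi <- pmin(floor(y[inside]), d[2L] - 2L); yf <- y[inside] - yi
  zi <- pmin(floor(z[inside]), d[3L] - 2L); zf <- z[inside] - zi
  # handle degenerate single-slab dimensions
  if (d[1L] == 1L) { xi <- rep(0, sum(inside)); xf <- xf * 0 }
  if (d[2L] == 1L) { yi <- rep(0, sum(inside)); yf <- yf * 0 }
  if (d[3L] == 1L) { zi <- rep(0, sum(inside)); zf <- zf * 0 }
  at <- function(dx, dy, dz) {
    img[cbind(xi + dx + 1L, yi + dy + 1L, zi + dz + 1L)]
  }
  out[inside] <-
    at(0L, 0L, 0L) * (1 - xf) * (1 - yf) * (1 - zf) +
    at(1L, 0L, 0L) * xf * (1 - yf) * (1 - zf) +
    at(0L, 1L, 0L) * (1 - xf) * yf * (1 - zf) +
    at(0L, 0L, 1L) * (1 - xf) * (1 - yf) * zf +
    at(1L, 1L, 0L) * xf * yf * (1 - zf) +
    at(1L, 0L, 1L) * xf * (1 - yf) * zf +
    at(0L, 1L, 1L) * (1 - xf) * yf * zf +
    at(1L, 1L, 1L) * xf * yf * zf

  list(data = array(out, ref_dim),
       in_field = array(inside, ref_dim))
}

#' Segment the contrast-enhancing lesion by intensity thresholding
#'
#' Semiautomatic enhancing-lesion segmentation on the T1 subtraction image
#' (post- minus pre-contrast): voxels above mean + `k_sd` * SD of the
#' subtraction signal over non-enhancing brain are candidates; connected
#' components (6-connectivity) smaller than `min_component_voxels` are
#' dropped; if seed points are supplied only seeded components are kept.
#' Finding no voxel above threshold is not an error: an empty mask is
#' returned with a warning.
#'
#' @param post_t1,pre_t1 3D arrays on the same grid.
#' @param brain_mask Logical 3D array of brain voxels used for the noise
#'   statistics.
#' @param k_sd Threshold in SD units above the non-enhancing mean. Default 3.
#' @param min_component_voxels Minimum voxels per retained component.
#'   Default 10.
#' @param seeds Optional matrix of 1-based voxel indices (rows = points,
#'   3 columns); only components containing a seed are kept.
#' @return Object of class `lesion_mask`: logical `mask`, `n_components`,
#'   `component_labels` (integer array), `threshold` used, and `volume_ml`
#'   when `voxel_mm` is given.
#' @param voxel_mm Optional length-3 voxel size (mm) used to report volume.
#' @export
segment_enhancing <- function(post_t1, pre_t1, brain_mask, k_sd = 3,
                              min_component_voxels = 10L, seeds = NULL,
                              voxel_mm = NULL) {
  if (!identical(dim(post_t1), dim(pre_t1)) ||
      !identical(dim(post_t1), dim(brain_mask)))
    stop_gliopred("post, pre and brain mask must share one grid",
                  "gliopred_geometry_error")
  sub <- post_t1 - pre_t1
  vals <- sub[brain_mask]
  thr <- mean(vals) + k_sd * stats::sd(vals)
  cand <- sub > thr & brain_mask

  labels <- label_components_3d(cand)
  keep <- integer(0)
  if (any(cand)) {
    tab <- table(labels[labels > 0L])
    keep <- as.integer(names(tab)[tab >= min_component_voxels])
    if (!is.null(seeds)) {
      seeds <- as.matrix(seeds)
      seeded <- unique(labels[seeds])
      keep <- intersect(keep, seeded[seeded > 0L])
    }
  }
  mask <- array(labels %in% keep, dim(sub))
  if (!any(mask))
    warn_gliopred("no enhancing voxels above threshold; returning empty mask",
                  "gliopred_empty_mask_warning")
  component_labels <- labels
  component_labels[!mask] <- 0L
  structure(list(mask = mask, n_components = length(keep),
                 component_labels = component_labels, threshold = thr,
                 volume_ml = if (!is.null(voxel_mm))
                   sum(mask) * prod(voxel_mm) / 1000 else NA_real_),
            class = "lesion_mask")
}

#' Extract the per-lesion feature vector
#'
#' Summarizes the aligned maps over the enhancing-lesion mask: medians of
#' MD, FA, CL, CP and CS; MD_min as the 10th percentile of MD; and rCBV_max
#' as the 90th percentile of rCBV. Percentiles use linear interpolation
#' between order statistics by default (`convention = "interpolated"`); the
#' alternative reading — mean of the tail beyond the percentile — is
#' selectable and recorded in the output. Non-finite voxels are excluded and
#' counted.
#'
#' @param mask Logical 3D array or a [segment_enhancing()] result.
#' @param maps Named list of aligned 3D arrays; recognized names `md`, `fa`,
#'   `cl`, `cp`, `cs`, `rcbv` (any subset containing `fa`, `cl`, `rcbv`).
#' @param lesion_id Identifier copied into the output row.
#' @param convention Percentile convention, `"interpolated"` (default) or
#'   `"tail_mean"`.
#' @return One-row `data.frame` with `lesion_id`, `fa_median`, `cl_median`,
#'   `rcbv_max`, and when available `md_median`, `md_min`, `cp_median`,
#'   `cs_median`, plus `n_voxels`, `n_excluded`, `percentile_convention`.
#' @export
extract_features <- function(mask, maps, lesion_id = "lesion",
                             convention = c("interpolated", "tail_mean")) {
  convention <- match.arg(convention)
  if (inherits(mask, "lesion_mask")) mask <- mask$mask
  if (!is.logical(mask))
    stop_gliopred("'mask' must be logical", "gliopred_validation_error")
  for (m in maps) {
    if (!identical(dim(m), dim(mask)))
      stop_gliopred("all maps must share the mask grid",
                    "gliopred_geometry_error")
  }
  idx <- which(mask)
  if (length(idx) == 0L)
    stop_gliopred("empty lesion mask: no voxels to extract features from",
                  "gliopred_feature_extraction_error")

  grab <- function(name) if (name %in% names(maps)) maps[[name]][idx] else NULL
  n_excluded <- 0L
  med <- function(x) {
    if (is.null(x)) return(NA_real_)
    bad <- !is.finite(x)
    n_excluded <<- n_excluded + sum(bad)
    stats::median(x[!bad])
  }
  pct <- function(x, p) {
    if (is.null(x)) return(NA_real_)
    lesion_percentile(x, p, convention)
  }

  fa <- grab("fa"); cl <- grab("cl"); rcbv <- grab("rcbv"); md <- grab("md")
  out <- data.frame(
    lesion_id = lesion_id,
    fa_median = med(fa),
    cl_median = med(cl),
    rcbv_max = pct(rcbv, 0.9),
    md_median = med(md),
    md_min = pct(md, 0.1),
    cp_median = med(grab("cp")),
    cs_median = med(grab("cs")),
    n_voxels = length(idx),
    n_excluded = n_excluded,
    percentile_convention = convention,
    stringsAsFactors = FALSE)
  out
}
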