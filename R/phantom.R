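# Digital phantom generator: seeded, self-verifying ground truth for every
# pipeline stage (DWI tensors, DSC perfusion with leakage, enhancing rim,
# planted TP/PsP feature regimes).

#' Quasi-uniform gradient direction set
#'
#' Deterministic Fibonacci-sphere direction set, used as the phantom's
#' diffusion-encoding scheme (30 noncollinear directions by default).
#'
#' @param n Number of directions.
#' @return 3 x n matrix of unit vectors.
#' @export
fibonacci_directions <- function(n = 30L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- 2.399963229728653 * (seq_len(n) - 1L)  # golden angle
  rbind(cos(phi) * r, sin(phi) * r, z)
}

#' Specification of a digital response-assessment phantom
#'
#' Defines the geometry, tissue regimes, acquisition parameters and noise of
#' a synthetic multiparametric study. Defaults mirror the reference
#' acquisition (1.72 x 1.72 x 3 mm voxels, 30-direction b = 0/1000 DWI, 45
#' DSC frames at TR/TE = 2000/45 ms) on a compact grid, with baseline SNR 50.
#' The planted `class` selects the enhancing-rim regime: `"TP"` plants a
#' high-FA, moderate-CL, high-rCBV rim; `"PsP"` a near-isotropic low-rCBV
#' rim. Both regimes sit at least 2 logit units from the PP = 0.5 decision
#' surface of the default [prediction_model()], so class labels are stable
#' under the default noise.
#'
#' @param class Planted lesion class, `"TP"` or `"PsP"`.
#' @param seed Integer RNG seed; identical seeds give identical phantoms.
#' @param grid Grid dimensions (voxels).
#' @param voxel_mm Voxel size (mm).
#' @param snr Baseline signal-to-noise ratio (b0 DWI and DSC baseline);
#'   `Inf` for noise-free.
#' @param n_directions Diffusion directions at b = 1000 s/mm^2.
#' @param n_frames DSC frames.
#' @param te_ms,tr_ms DSC echo/repetition times (ms).
#' @param bolus_t0_s Bolus onset (s).
#' @param gv_alpha,gv_beta_s Gamma-variate shape and time scale of the
#'   first-pass response.
#' @param rim_k2 Planted leakage constant in the enhancing rim (1/s^2).
#' @param rim_rcbv Planted rim rCBV scale; default depends on `class`.
#' @param rim_lambda Planted rim eigenvalue triple (mm^2/s); default depends
#'   on `class`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(class = c("TP", "PsP"), seed = 1L,
                         grid = c(28L, 28L, 10L),
                         voxel_mm = c(1.72, 1.72, 3),
                         snr = 50, n_directions = 30L, n_frames = 45L,
                         te_ms = 45, tr_ms = 2000, bolus_t0_s = 24,
                         gv_alpha = 3, gv_beta_s = 3.5,
                         rim_k2 = 0.03,
                         rim_rcbv = NULL, rim_lambda = NULL) {
  class <- match.arg(class)
  if (is.null(rim_rcbv)) rim_rcbv <- if (class == "TP") 4.0 else 1.3
  if (is.null(rim_lambda))
    rim_lambda <- if (class == "TP") c(1.50, 1.35, 0.60) * 1e-3
                  else c(0.95, 0.85, 0.80) * 1e-3
  if (snr <= 0)
    stop_gliopred("'snr' must be positive (use Inf for noise-free)",
                  "gliopred_validation_error")
  spec <- structure(list(
    class = class, seed = as.integer(seed), grid = as.integer(grid),
    voxel_mm = voxel_mm, snr = snr, n_directions = as.integer(n_directions),
    n_frames = as.integer(n_frames), te_ms = te_ms, tr_ms = tr_ms,
    bolus_t0_s = bolus_t0_s, gv_alpha = gv_alpha, gv_beta_s = gv_beta_s,
    rim_k2 = rim_k2, rim_rcbv = rim_rcbv, rim_lambda = rim_lambda,
    background_lambda = rep(0.75e-3, 3L),
    core_lambda = rep(1.5e-3, 3L),
    lesion_center_vox = c(9, 14, 5),
    core_radius_mm = 4, rim_radius_mm = 8,
    reference_center_vox = c(21, 14, 5), reference_half_vox = c(2L, 2L, 1L),
    s0_dwi = 1000, s0_dsc = 500, t1_brain = 100, t1_air = 20,
    t1_noise_sd = 2, rim_enhancement = 40),
    class = "phantom_spec")
  # geometry sanity: lesion must fit inside the grid
  ctr_mm <- spec$lesion_center_vox * spec$voxel_mm
  ext_mm <- spec$grid * spec$voxel_mm
  if (any(ctr_mm - spec$rim_radius_mm < 0) ||
      any(ctr_mm + spec$rim_radius_mm > ext_mm))
    stop_gliopred("lesion does not fit inside the phantom grid",
                  "gliopred_validation_error")
  spec
}

# Euclidean distance (mm) of every voxel center from a voxel-coordinate point.
.dist_mm <- function(grid, voxel_mm, center_vox) {
  d <- array(0, grid)
  cx <- (center_vox - 1) * voxel_mm  # 0-based centers
  x <- ((seq_len(grid[1L]) - 1) * voxel_mm[1L] - cx[1L])^2
  y <- ((seq_len(grid[2L]) - 1) * voxel_mm[2L] - cx[2L])^2
  z <- ((seq_len(grid[3L]) - 1) * voxel_mm[3L] - cx[3L])^2
  outer(outer(x, y, "+"), z, "+")^0.5
}

#' Generate a seeded digital phantom study
#'
#' Builds the full synthetic study from a [phantom_spec()]: a 4D DWI volume
#' forward-simulated from the planted tensor field with Rician noise; a 4D
#' DSC series with a gamma-variate first-pass response scaled by the planted
#' CBV field, a leakage term driven by the planted K2 in the rim, and
#' Gaussian noise; pre/post-contrast T1 volumes with a deterministic
#' enhancing rim; brain and contralateral white-matter reference masks; and
#' a ground-truth block (per-voxel eigenvalues, scalar maps, CBV/K2 fields,
#' rim mask, true feature vector and class label). Generation is
#' deterministic: the same spec and seed give identical volumes. The truth
#' features are checked against the planted class under the default model
#' at build time.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `gliopred_phantom` with components `dwi`,
#'   `protocol`, `dsc` (a [perfusion_series()]), `pre_t1`, `post_t1`,
#'   `brain_mask`, `reference_mask`, `affine`, `voxel_mm`, `truth`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  g <- spec$grid
  dist_les <- .dist_mm(g, spec$voxel_mm, spec$lesion_center_vox)
  core <- dist_les <= spec$core_radius_mm
  rim <- dist_les <= spec$rim_radius_mm & !core

  brain <- array(TRUE, g)
  brain[c(1L, g[1L]), , ] <- FALSE
  brain[, c(1L, g[2L]), ] <- FALSE

  ref <- array(FALSE, g)
  rc <- spec$reference_center_vox; rh <- spec$reference_half_vox
  ref[(rc[1L] - rh[1L]):(rc[1L] + rh[1L]),
      (rc[2L] - rh[2L]):(rc[2L] + rh[2L]),
      (rc[3L] - rh[3L]):(rc[3L] + rh[3L])] <- TRUE
  ref <- ref & !rim & !core

  # ---- planted tensor field (axis-aligned eigenframes) ----
  l1 <- array(spec$background_lambda[1L], g)
  l2 <- array(spec$background_lambda[2L], g)
  l3 <- array(spec$background_lambda[3L], g)
  l1[rim] <- spec$rim_lambda[1L]; l2[rim] <- spec$rim_lambda[2L]
  l3[rim] <- spec$rim_lambda[3L]
  l1[core] <- spec$core_lambda[1L]; l2[core] <- spec$core_lambda[2L]
  l3[core] <- spec$core_lambda[3L]

  protocol <- diffusion_protocol(
    bvals = c(0, rep(1000, spec$n_directions)),
    bvecs = cbind(c(0, 0, 0), fibonacci_directions(spec$n_directions)))

  nvol <- length(protocol$bvals)
  nvox <- prod(g)
  # signals per regime (tensor diagonal in each regime), assembled per voxel
  regime <- array(1L, g); regime[rim] <- 2L; regime[core] <- 3L
  regime_lambda <- list(spec$background_lambda, spec$rim_lambda,
                        spec$core_lambda)
  sig <- matrix(0, nvox, nvol)
  for (r in 1:3) {
    s <- simulate_dwi_signal(diag(regime_lambda[[r]]), protocol,
                             s0 = spec$s0_dwi)
    sig[regime == r, ] <- matrix(s, sum(regime == r), nvol, byrow = TRUE)
  }
  sig[!brain, ] <- spec$s0_dwi * 0.05
  if (is.finite(spec$snr))
    sig <- add_rician_noise(sig, spec$s0_dwi / spec$snr)
  dwi <- array(sig, c(g, nvol))

  # ---- DSC series ----
  tt <- (seq_len(spec$n_frames) - 1L) * spec$tr_ms / 1000
  # reference first-pass curve: unit-CBV gamma-variate, peak ~10 1/s
  peak_target <- 10
  Kref <- peak_target /
    (spec$gv_alpha * spec$gv_beta_s)^spec$gv_alpha / exp(-spec$gv_alpha)
  ref_curve <- gamma_variate(tt, Kref, spec$bolus_t0_s, spec$gv_alpha,
                             spec$gv_beta_s)
  cum_ref <- cumtrapz(tt, ref_curve)

  # regime scale times a smooth deterministic perfusion modulation, so the
  # planted CBV field varies voxel-to-voxel as real perfusion does; the
  # field is renormalized to mean 1 over the reference ROI so the planted
  # rCBV is the field itself
  ix <- slice.index(array(0, g), 1L); iy <- slice.index(array(0, g), 2L)
  iz <- slice.index(array(0, g), 3L)
  modf <- 1 + 0.25 * sin(2 * pi * ix / g[1L]) * cos(2 * pi * iy / g[2L]) +
    0.15 * cos(2 * pi * iz / g[3L])
  cbv_scale <- array(1, g)
  cbv_scale[rim] <- spec$rim_rcbv
  cbv_scale[core] <- 0.5
  cbv_scale <- cbv_scale * modf
  cbv_scale[!brain] <- 0
  cbv_scale <- cbv_scale / mean(cbv_scale[ref])
  k2 <- array(0, g)
  k2[rim] <- spec$rim_k2

  dr2 <- tcrossprod(as.numeric(cbv_scale), ref_curve) -
    tcrossprod(as.numeric(k2), cum_ref)
  dsc_sig <- spec$s0_dsc * exp(-(spec$te_ms / 1000) * dr2)
  if (is.finite(spec$snr))
    dsc_sig <- dsc_sig + stats::rnorm(length(dsc_sig),
                                      0, spec$s0_dsc / spec$snr)
  dsc <- perfusion_series(array(dsc_sig, c(g, spec$n_frames)),
                          te_ms = spec$te_ms, tr_ms = spec$tr_ms)

  # ---- T1 pair with deterministic rim enhancement ----
  pre <- array(spec$t1_air, g)
  pre[brain] <- spec$t1_brain
  pre <- pre + stats::rnorm(nvox, 0, spec$t1_noise_sd)
  post <- pre + spec$rim_enhancement * rim +
    stats::rnorm(nvox, 0, spec$t1_noise_sd)

  # ---- ground truth ----
  truth_field <- list(lambda1 = l1, lambda2 = l2, lambda3 = l3)
  truth_maps <- scalar_maps(truth_field)
  truth_rcbv <- cbv_scale  # reference regime has scale 1 by construction
  maps <- list(md = truth_maps$md, fa = truth_maps$fa, cl = truth_maps$cl,
               cp = truth_maps$cp, cs = truth_maps$cs, rcbv = truth_rcbv)
  truth_features <- extract_features(rim, maps, lesion_id = "phantom")
  pp <- compute_pp(truth_features$fa_median, truth_features$cl_median,
                   truth_features$rcbv_max)
  if (classify_response(pp) != spec$class)
    stop_gliopred("planted regime does not reproduce the planted class",
                  "gliopred_validation_error")

  affine <- diag(c(spec$voxel_mm, 1))
  structure(list(
    dwi = dwi, protocol = protocol, dsc = dsc,
    pre_t1 = pre, post_t1 = post,
    brain_mask = brain, reference_mask = ref,
    affine = affine, voxel_mm = spec$voxel_mm,
    truth = list(lambda1 = l1, lambda2 = l2, lambda3 = l3,
                 maps = truth_maps, cbv_scale = cbv_scale, k2 = k2,
                 rim_mask = rim, core_mask = core,
                 features = truth_features, pp = pp, label = spec$class),
    spec = spec),
    class = "gliopred_phantom")
}

#' @export
print.gliopred_phantom <- function(x, ...) {
  cat(sprintf(
    "Digital response-assessment phantom (%s regime, seed %d)\n",
    x$spec$class, x$spec$seed))
  cat(sprintf("  grid %s, voxel %s mm\n",
              paste(x$spec$grid, collapse = "x"),
              paste(signif(x$voxel_mm, 3), collapse = "x")))
  cat(sprintf("  truth: FA %.3f, CL %.3f, rCBV_max %.2f -> PP %.3f (%s)\n",
              x$truth$features$fa_median, x$truth$features$cl_median,
              x$truth$features$rcbv_max, x$truth$pp, x$truth$label))
  invisible(x)
}
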