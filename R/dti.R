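#' Diffusion acquisition protocol
#'
#' Bundles and validates the b-values and gradient directions of a DWI
#' acquisition. The reference acquisition uses one b = 0 volume plus 30
#' noncollinear directions at b = 1000 s/mm^2, but any protocol with at least
#' six unique non-zero-b directions (seven usable measurements) is accepted.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs 3 x n matrix of gradient directions, columns matching
#'   `bvals`. Directions for b > 0 must be unit-norm within 1e-6; b = 0
#'   entries may be zero vectors.
#' @return An object of class `diffusion_protocol`.
#' @export
diffusion_protocol <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop_gliopred("'bvecs' must be a 3 x length(bvals) matrix",
                  "gliopred_protocol_error")
  if (anyNA(bvals) || any(bvals < 0))
    stop_gliopred("b-values must be non-negative and non-missing",
                  "gliopred_protocol_error")
  dw <- bvals > 0
  if (length(bvals) < 7L)
    stop_gliopred("at least 7 measurements (1 b0 + 6 directions) are required",
                  "gliopred_protocol_error")
  norms <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    stop_gliopred("gradient directions for b > 0 must be unit vectors",
                  "gliopred_protocol_error")
  uniq <- unique(round(t(bvecs[, dw, drop = FALSE]), 6L))
  if (nrow(uniq) < 6L)
    stop_gliopred("at least 6 unique diffusion-encoding directions required",
                  "gliopred_protocol_error")
  structure(list(bvals = bvals, bvecs = bvecs, n_b0 = sum(!dw)),
            class = "diffusion_protocol")
}

#' Fit per-voxel diffusion tensors by log-linear least squares
#'
#' Estimates a symmetric 3x3 diffusion tensor D per voxel from the DWI signal
#' model \eqn{S_i = S_0 \exp(-b_i\, g_i^T D g_i)}. The log-signal is fit by
#' least squares over the 7 parameters (ln S0 and the 6 unique tensor
#' elements); weighted least squares (weights \eqn{S_i^2}, the first-order
#' variance correction for log-transformed noise) is available via
#' `weighted = TRUE`. Negative eigenvalues are clamped to zero and flagged.
#' Voxels with a non-positive signal in any volume are invalidated rather
#' than aborting the fit.
#'
#' @param dwi 4D numeric array (x, y, z, volume), one volume per protocol
#'   entry.
#' @param protocol A [diffusion_protocol()].
#' @param mask Optional logical 3D array restricting the fit.
#' @param weighted Use signal-squared weighted least squares instead of the
#'   ordinary fit. Default `FALSE`.
#' @return An object of class `tensor_field`: arrays of sorted eigenvalues
#'   (`lambda1 >= lambda2 >= lambda3`, mm^2/s), the 6 tensor components,
#'   a validity mask and clamp flags.
#' @export
fit_tensor <- function(dwi, protocol, mask = NULL, weighted = FALSE) {
  stopifnot(inherits(protocol, "diffusion_protocol"))
  if (length(dim(dwi)) != 4L)
    stop_gliopred("'dwi' must be a 4D array", "gliopred_protocol_error")
  dims <- dim(dwi)
  if (dims[4L] != length(protocol$bvals))
    stop_gliopred("number of DWI volumes must match the protocol",
                  "gliopred_protocol_error")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))

  nvol <- dims[4L]
  g <- protocol$bvecs
  b <- protocol$bvals
  # design: ln S = ln S0 - b * (gx^2 Dxx + gy^2 Dyy + gz^2 Dzz
  #                             + 2 gx gy Dxy + 2 gx gz Dxz + 2 gy gz Dyz)
  X <- cbind(1,
             -b * g[1L, ]^2, -b * g[2L, ]^2, -b * g[3L, ]^2,
             -2 * b * g[1L, ] * g[2L, ],
             -2 * b * g[1L, ] * g[3L, ],
             -2 * b * g[2L, ] * g[3L, ])

  vox <- which(mask)
  sig <- matrix(aperm(dwi, c(4L, 1L, 2L, 3L)), nrow = nvol)[, vox, drop = FALSE]
  usable <- colSums(sig <= 0) == 0L
  n_masked <- length(vox)

  coefs <- matrix(NA_real_, 7L, n_masked)
  if (any(usable)) {
    logs <- log(sig[, usable, drop = FALSE])
    if (!weighted) {
      coefs[, usable] <- qr.coef(qr(X), logs)
    } else {
      w <- sig[, usable, drop = FALSE]^2
      for (j in seq_len(sum(usable))) {
        coefs[, which(usable)[j]] <-
          qr.coef(qr(X * sqrt(w[, j])), logs[, j] * sqrt(w[, j]))
      }
    }
  }

  lam <- matrix(NA_real_, 3L, n_masked)
  clamped <- logical(n_masked)
  for (j in seq_len(n_masked)) {
    if (!usable[j]) next
    d <- coefs[2:7, j]
    D <- matrix(c(d[1L], d[4L], d[5L],
                  d[4L], d[2L], d[6L],
                  d[5L], d[6L], d[3L]), 3L, 3L)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values # decreasing
    if (any(ev < 0)) {
      clamped[j] <- TRUE
      ev <- pmax(ev, 0)
    }
    lam[, j] <- ev
  }

  shape3 <- dims[1:3]
  to_arr <- function(v) { a <- array(NA_real_, shape3); a[vox] <- v; a }
  valid <- array(FALSE, shape3); valid[vox] <- usable
  clampf <- array(FALSE, shape3); clampf[vox] <- clamped
  tensor <- array(NA_real_, c(shape3, 6L))
  for (k in 1:6) {
    a <- array(NA_real_, shape3); a[vox] <- coefs[k + 1L, ]
    tensor[, , , k] <- a
  }

  structure(list(
    lambda1 = to_arr(lam[1L, ]), lambda2 = to_arr(lam[2L, ]),
    lambda3 = to_arr(lam[3L, ]),
    tensor = tensor,  # Dxx, Dyy, Dzz, Dxy, Dxz, Dyz
    valid = valid, clamped = clampf, mask = mask,
    protocol = protocol),
    class = "tensor_field")
}

#' Scalar maps from a diffusion tensor field
#'
#' Derives the standard rotation-invariant maps from sorted eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \lambda_3 \ge 0}:
#' mean diffusivity MD = trace/3; fractional anisotropy
#' \eqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i - MD)^2} / \sqrt{\sum_i \lambda_i^2}};
#' and the Westin shape coefficients in the sum-normalized convention,
#' CL = (l1 - l2)/suml, CP = 2(l2 - l3)/suml, CS = 3 l3/suml, which satisfy
#' CL + CP + CS = 1 wherever the trace is positive. Zero tensors get
#' FA = CL = CP = 0 and CS = 1 by convention, and are flagged.
#'
#' @param field A [fit_tensor()] result, or a list with sorted non-negative
#'   eigenvalue arrays `lambda1`, `lambda2`, `lambda3`.
#' @return A list of class `scalar_maps` with arrays `md` (mm^2/s), `fa`,
#'   `cl`, `cp`, `cs` (dimensionless) and a `degenerate` flag array marking
#'   zero-trace voxels.
#' @export
scalar_maps <- function(field) {
  l1 <- field$lambda1; l2 <- field$lambda2; l3 <- field$lambda3
  bad <- which(is.finite(l1) & is.finite(l2) & is.finite(l3) &
                 (l1 < l2 - 1e-15 | l2 < l3 - 1e-15 | l3 < -1e-15))
  if (length(bad) > 0L)
    stop_gliopred("eigenvalues must be sorted descending and non-negative",
                  "gliopred_internal_error")
  tr <- l1 + l2 + l3
  md <- tr / 3
  ss <- l1^2 + l2^2 + l3^2
  dev <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  fa <- sqrt(1.5) * sqrt(dev) / sqrt(ss)
  cl <- (l1 - l2) / tr
  cp <- 2 * (l2 - l3) / tr
  cs <- 3 * l3 / tr
  zero <- is.finite(tr) & tr <= 0
  fa[zero] <- 0; cl[zero] <- 0; cp[zero] <- 0; cs[zero] <- 1
  structure(list(md = md, fa = fa, cl = cl, cp = cp, cs = cs,
                 degenerate = zero),
            class = "scalar_maps")
}

#' Forward-simulate DWI signals from a known tensor
#'
#' Noise-free signal \eqn{S_i = S_0 \exp(-b_i\, g_i^T D g_i)} for a single
#' tensor, used for round-trip verification and phantom construction.
#'
#' @param D Symmetric 3x3 tensor (mm^2/s).
#' @param protocol A [diffusion_protocol()].
#' @param s0 Signal at b = 0.
#' @return Numeric vector, one signal per protocol entry.
#' @export
simulate_dwi_signal <- function(D, protocol, s0 = 1000) {
  stopifnot(inherits(protocol, "diffusion_protocol"))
  D <- as.matrix(D)
  stopifnot(identical(dim(D), c(3L, 3L)), max(abs(D - t(D))) < 1e-12)
  g <- protocol$bvecs
  q <- colSums(g * (D %*% g))
  s0 * exp(-protocol$bvals * q)
}

#' Add Rician noise to magnitude MR signals
#'
#' Magnitude of the complex signal after adding independent Gaussian noise of
#' standard deviation `sigma` to the real and imaginary channels:
#' \eqn{\sqrt{(S + n_1)^2 + n_2^2}}.
#'
#' @param signal Numeric vector or array of noise-free magnitudes.
#' @param sigma Gaussian channel standard deviation (same units as signal).
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0)
    stop_gliopred("'sigma' must be non-negative", "gliopred_validation_error")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
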