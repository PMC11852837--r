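#' Dynamic susceptibility contrast (DSC) series container
#'
#' Validates and bundles a 4D DSC acquisition: the T2*-weighted signal
#' S(x, t), the echo time and repetition time, and (optionally) a baseline
#' window of pre-bolus frames. The reference acquisition is 45 frames at
#' TR/TE = 2000/45 ms.
#'
#' @param signal 4D numeric array (x, y, z, t).
#' @param te_ms Echo time in milliseconds (> 0).
#' @param tr_ms Repetition time in milliseconds (> 0); frame spacing.
#' @param baseline Optional integer vector of baseline frame indices
#'   preceding bolus arrival.
#' @return An object of class `perfusion_series` with a `time_s` vector.
#' @export
perfusion_series <- function(signal, te_ms, tr_ms, baseline = NULL) {
  if (length(dim(signal)) != 4L)
    stop_gliopred("'signal' must be a 4D array", "gliopred_protocol_error")
  nt <- dim(signal)[4L]
  if (nt < 10L)
    stop_gliopred("at least 10 time points are required",
                  "gliopred_protocol_error")
  if (!is_scalar_number(te_ms) || te_ms <= 0)
    stop_gliopred("'te_ms' must be a positive number",
                  "gliopred_protocol_error")
  if (!is_scalar_number(tr_ms) || tr_ms <= 0)
    stop_gliopred("'tr_ms' must be a positive number",
                  "gliopred_protocol_error")
  if (!is.null(baseline)) {
    baseline <- as.integer(baseline)
    if (length(baseline) == 0L || any(baseline < 1L) || any(baseline > nt))
      stop_gliopred("'baseline' must be a non-empty set of frame indices",
                    "gliopred_protocol_error")
  }
  structure(list(signal = signal, te_ms = te_ms, tr_ms = tr_ms,
                 baseline = baseline, n_timepoints = nt,
                 time_s = (seq_len(nt) - 1L) * tr_ms / 1000),
            class = "perfusion_series")
}

#' Convert DSC signals to relaxation-rate change curves
#'
#' Applies the single-compartment first-pass relation
#' \eqn{\Delta R_2^*(t) = -\ln(S(t)/S_0)/TE} per voxel, with S0 the mean
#' signal over the baseline window. Voxels whose baseline mean is
#' non-positive, or whose signal is non-positive at any frame, are flagged
#' invalid and excluded instead of raising an error.
#'
#' @param series A [perfusion_series()] with a baseline window set (or pass
#'   `baseline` here).
#' @param mask Optional logical 3D array of voxels to convert.
#' @param baseline Baseline frame indices; defaults to the window stored in
#'   `series`.
#' @return Object of class `conc_field`: matrix `delta_r2` (voxel x time,
#'   1/s), voxel linear indices `vox`, `valid` flags, `time_s`, and the
#'   baseline window.
#' @export
to_concentration <- function(series, mask = NULL, baseline = series$baseline) {
  stopifnot(inherits(series, "perfusion_series"))
  if (is.null(baseline) || length(baseline) == 0L)
    stop_gliopred("a non-empty baseline window is required",
                  "gliopred_protocol_error")
  dims <- dim(series$signal)
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  vox <- which(mask)
  nt <- dims[4L]
  sig <- matrix(series$signal, ncol = nt)[vox, , drop = FALSE]
  s0 <- rowMeans(sig[, baseline, drop = FALSE])
  valid <- s0 > 0 & rowSums(sig <= 0) == 0L
  te_s <- series$te_ms / 1000
  dr2 <- matrix(NA_real_, length(vox), nt)
  if (any(valid))
    dr2[valid, ] <- -log(sig[valid, , drop = FALSE] / s0[valid]) / te_s
  structure(list(delta_r2 = dr2, vox = vox, valid = valid,
                 dims = dims[1:3], s0 = s0, time_s = series$time_s,
                 baseline = as.integer(baseline)),
            class = "conc_field")
}

#' Detect bolus arrival on the mask-mean concentration curve
#'
#' The arrival frame is the first frame at which the mean \eqn{\Delta R_2^*}
#' curve over valid voxels exceeds (provisional baseline mean) + k * SD. The
#' returned baseline window is every frame before arrival minus one guard
#' frame. A window shorter than `min_baseline` frames triggers a degraded-
#' baseline warning; a curve that never crosses the threshold is an error.
#'
#' @param conc A [to_concentration()] result (a provisional baseline of the
#'   first few frames is fine for detection).
#' @param k Threshold in baseline standard deviations. Default 3.
#' @param min_baseline Minimum acceptable number of baseline frames.
#'   Default 5.
#' @param guard Frames removed just before arrival. Default 1.
#' @return List with `arrival` (frame index) and `baseline` (frame indices).
#' @export
detect_bolus <- function(conc, k = 3, min_baseline = 5L, guard = 1L) {
  stopifnot(inherits(conc, "conc_field"))
  if (!any(conc$valid))
    stop_gliopred("no valid voxels to detect a bolus on",
                  "gliopred_no_bolus_error")
  mcurve <- colMeans(conc$delta_r2[conc$valid, , drop = FALSE])
  prov <- conc$baseline
  mu <- mean(mcurve[prov]); sdv <- stats::sd(mcurve[prov])
  if (!is.finite(sdv) || sdv == 0) sdv <- 1e-12
  # floor the threshold at 5% of the dynamic range: a short provisional
  # baseline underestimates the frame-mean SD and would trigger early
  thr <- mu + max(k * sdv, 0.05 * (max(mcurve) - mu))
  above <- mcurve > thr
  # require the crossing to be sustained on the next frame too: the mask
  # mean has a very small SD, so an isolated fluctuation can cross k*SD
  sustained <- which(above & c(above[-1L], TRUE))
  sustained <- sustained[sustained > min(prov)]
  if (length(sustained) == 0L)
    stop_gliopred("no frame exceeds the bolus-detection threshold",
                  "gliopred_no_bolus_error")
  arrival <- min(sustained)
  baseline <- seq_len(max(arrival - 1L - guard, 1L))
  if (length(baseline) < min_baseline)
    warn_gliopred(sprintf(
      "only %d baseline frames before bolus arrival (wanted >= %d); baseline estimate degraded",
      length(baseline), min_baseline), "gliopred_degraded_baseline_warning")
  list(arrival = arrival, baseline = baseline)
}

#' Gamma-variate first-pass bolus model
#'
#' \eqn{c(t) = K (t - t_0)^\alpha \exp(-(t - t_0)/\beta)} for t > t0 and 0
#' before, the standard approximation of the first-pass response in the
#' absence of recirculation. Its peak is at \eqn{t_0 + \alpha\beta} and its
#' full-support integral is \eqn{K \beta^{\alpha+1} \Gamma(\alpha+1)}.
#'
#' @param t Time (s), vectorized.
#' @param K Amplitude (1/s per s^alpha).
#' @param t0 Bolus onset time (s).
#' @param alpha Shape parameter (> 0).
#' @param beta Time scale (s, > 0).
#' @return Curve values, same length as `t`.
#' @export
gamma_variate <- function(t, K, t0, alpha, beta) {
  dt <- pmax(t - t0, 0)
  ifelse(dt > 0, K * dt^alpha * exp(-dt / beta), 0)
}

#' Closed-form full-support integral of the gamma-variate
#' @inheritParams gamma_variate
#' @return \eqn{K \beta^{\alpha+1} \Gamma(\alpha+1)}.
#' @export
gamma_variate_integral <- function(K, alpha, beta) {
  K * beta^(alpha + 1) * gamma(alpha + 1)
}

#' Fit a gamma-variate to a first-pass concentration curve
#'
#' Initialization scans a grid of onset times t0 between the baseline and the
#' curve peak; for each candidate the model is log-linearized
#' (\eqn{\ln c = \ln K + \alpha \ln(t - t_0) - (t - t_0)/\beta}) and solved by
#' linear least squares. The best candidate seeds a bounded Levenberg-
#' Marquardt refinement ([minpack.lm::nlsLM()]). Non-convergence after
#' restarts returns a fit flagged `converged = FALSE` so callers can fall
#' back to raw-curve integration.
#'
#' @param t Time vector (s).
#' @param y Concentration curve (1/s), same length.
#' @param window Optional index range to fit over (should contain rise and
#'   peak); defaults to all frames.
#' @return Object of class `gamma_variate_fit`: `K`, `t0`, `alpha`, `beta`,
#'   `peak_time`, `resid_norm`, `converged`, and `fitted` values over `t`.
#' @export
fit_gamma_variate <- function(t, y, window = NULL) {
  stopifnot(length(t) == length(y))
  if (is.null(window)) window <- seq_along(t)
  tw <- t[window]; yw <- y[window]
  pk <- which.max(yw)
  if (pk < 3L)
    stop_gliopred("first-pass window must contain the rise and the peak",
                  "gliopred_validation_error")
  t0_grid <- unique(pmax(tw[1L] - diff(range(tw)) * 0.05,
                         seq(tw[1L] - (tw[2L] - tw[1L]), tw[pk - 1L],
                             length.out = 25L)))
  best <- NULL
  for (t0c in t0_grid) {
    sel <- tw > t0c & yw > max(yw) * 1e-3
    if (sum(sel) < 4L) next
    lt <- log(tw[sel] - t0c)
    co <- tryCatch(stats::lm.fit(cbind(1, lt, -(tw[sel] - t0c)),
                                 log(yw[sel]))$coefficients,
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co) || co[2L] <= 0 || co[3L] <= 0) next
    pars <- c(K = unname(exp(co[1L])), t0 = t0c, alpha = unname(co[2L]),
              beta = unname(1 / co[3L]))
    rss <- sum((gamma_variate(tw, pars[1L], pars[2L], pars[3L], pars[4L]) -
                  yw)^2)
    if (is.null(best) || rss < best$rss) best <- list(pars = pars, rss = rss)
  }
  if (is.null(best))
    stop_gliopred("could not initialize a gamma-variate fit",
                  "gliopred_fit_failure")
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yw ~ gamma_variate(tw, K, t0, alpha, beta),
      start = as.list(best$pars),
      lower = c(K = 0, t0 = tw[1L] - diff(range(tw)), alpha = 1e-3,
                beta = 1e-3),
      upper = c(K = Inf, t0 = tw[pk], alpha = 50, beta = diff(range(tw))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- best$pars
    converged <- FALSE
    resid_norm <- sqrt(best$rss)
  } else {
    p <- stats::coef(fit)
    converged <- TRUE
    resid_norm <- sqrt(sum(stats::resid(fit)^2))
  }
  structure(list(K = unname(p["K"]), t0 = unname(p["t0"]),
                 alpha = unname(p["alpha"]), beta = unname(p["beta"]),
                 peak_time = unname(p["t0"] + p["alpha"] * p["beta"]),
                 resid_norm = resid_norm, converged = converged,
                 fitted = gamma_variate(t, p["K"], p["t0"], p["alpha"],
                                        p["beta"])),
            class = "gamma_variate_fit")
}

#' Correct concentration curves for contrast-agent leakage
#'
#' Two-parameter linear leakage model against the mean curve of
#' non-enhancing brain: each voxel curve is modelled as
#' \eqn{\Delta R_2^*(t) \approx K_1\, \bar{c}(t) - K_2 \int_0^t \bar{c}(\tau)
#' d\tau}, with (K1, K2) estimated per voxel by linear least squares. The
#' corrected curve adds the leakage term back:
#' corrected = measured + K2 * cumulative integral of the reference. On a
#' leak-free voxel the fitted K2 is ~0 and the curve is unchanged.
#'
#' @param curves Matrix (voxel x time) of \eqn{\Delta R_2^*} curves, or a
#'   `conc_field` (its valid rows are corrected in place).
#' @param reference Mean non-enhancing-brain curve (length = n frames),
#'   not identically zero.
#' @param time_s Frame times (s); required when `curves` is a bare matrix.
#' @return List with `corrected` (same shape as input curves), `k1`, `k2`
#'   per voxel.
#' @export
leakage_correct <- function(curves, reference, time_s = NULL) {
  is_field <- inherits(curves, "conc_field")
  if (is_field) {
    time_s <- curves$time_s
    mat <- curves$delta_r2
    rows <- which(curves$valid)
  } else {
    mat <- as.matrix(curves)
    rows <- seq_len(nrow(mat))
    if (is.null(time_s))
      stop_gliopred("'time_s' is required with a bare curve matrix",
                    "gliopred_validation_error")
  }
  if (all(abs(reference) < 1e-300) || all(reference == 0))
    stop_gliopred("reference curve is identically zero",
                  "gliopred_reference_error")
  cumref <- cumtrapz(time_s, reference)
  X <- cbind(reference, -cumref)
  co <- qr.coef(qr(X), t(mat[rows, , drop = FALSE]))
  k1 <- rep(NA_real_, nrow(mat)); k2 <- rep(NA_real_, nrow(mat))
  k1[rows] <- co[1L, ]; k2[rows] <- co[2L, ]
  corrected <- mat
  corrected[rows, ] <- mat[rows, , drop = FALSE] +
    tcrossprod(k2[rows], cumref)
  if (is_field) {
    out <- curves
    out$delta_r2 <- corrected
    list(corrected = out, k1 = k1, k2 = k2)
  } else {
    list(corrected = corrected, k1 = k1, k2 = k2)
  }
}

#' Cerebral blood volume by numeric integration
#'
#' CBV per voxel is the trapezoidal integral of the (leakage-corrected)
#' \eqn{\Delta R_2^*} curve over the first-pass window. Negative integrals
#' are clamped to zero and flagged.
#'
#' @param curves Matrix (voxel x time) or `conc_field` of corrected curves.
#' @param window Integer frame indices of the first-pass window; default all
#'   frames.
#' @param time_s Frame times (s); required for a bare matrix.
#' @return List with `cbv` (numeric per voxel, arbitrary units) and
#'   `clamped` flags.
#' @export
compute_cbv <- function(curves, window = NULL, time_s = NULL) {
  if (inherits(curves, "conc_field")) {
    time_s <- curves$time_s
    mat <- curves$delta_r2
  } else {
    mat <- as.matrix(curves)
    if (is.null(time_s))
      stop_gliopred("'time_s' is required with a bare curve matrix",
                    "gliopred_validation_error")
  }
  nt <- ncol(mat)
  if (is.null(window)) window <- seq_len(nt)
  window <- as.integer(window)
  if (any(window < 1L) || any(window > nt))
    stop_gliopred("integration window lies outside the series",
                  "gliopred_validation_error")
  tw <- time_s[window]
  seg <- diff(tw)
  yw <- mat[, window, drop = FALSE]
  cbv <- as.numeric((yw[, -1L, drop = FALSE] +
                       yw[, -length(window), drop = FALSE]) %*% seg) / 2
  clamped <- is.finite(cbv) & cbv < 0
  cbv[clamped] <- 0
  list(cbv = cbv, clamped = clamped)
}

#' Normalize CBV to contralateral normal white matter
#'
#' Relative CBV is the ratio of each voxel's CBV to the mean CBV over the
#' reference region of interest (contralateral normal-appearing white
#' matter), so the reference-ROI mean rCBV is 1 by construction.
#'
#' @param cbv Numeric vector or 3D array of CBV values.
#' @param reference_mask Logical mask (same length/shape) of reference
#'   voxels; must be non-empty with positive mean CBV.
#' @return rCBV, same shape as `cbv`.
#' @export
normalize_rcbv <- function(cbv, reference_mask) {
  if (length(cbv) != length(reference_mask))
    stop_gliopred("'cbv' and 'reference_mask' must have equal length",
                  "gliopred_validation_error")
  ref <- cbv[as.logical(reference_mask)]
  ref <- ref[is.finite(ref)]
  if (length(ref) == 0L)
    stop_gliopred("reference ROI is empty", "gliopred_normalization_error")
  m <- mean(ref)
  if (!is.finite(m) || m <= 0)
    stop_gliopred("reference ROI mean CBV must be positive",
                  "gliopred_normalization_error")
  cbv / m
}
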