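# DSC perfusion: concentration conversion, bolus detection, gamma-variate
# fitting, leakage correction, CBV integration and rCBV normalization.

# small helper: a 4D series from a single voxel curve
series_from_curve <- function(S, te = 45, tr = 2000) {
  perfusion_series(array(S, c(1, 1, 1, length(S))), te_ms = te, tr_ms = tr)
}

test_that("constant signal converts to zero concentration", {
  s <- series_from_curve(rep(400, 45))
  conc <- to_concentration(s, baseline = 1:8)
  expect_true(all(abs(conc$delta_r2) < 1e-12))
})

test_that("conversion inverts the exponential forward signal model", {
  tt <- (0:44) * 2
  c_true <- gamma_variate(tt, K = 0.2, t0 = 20, alpha = 3, beta = 4)
  te_s <- 0.045
  S <- 500 * exp(-te_s * c_true)
  conc <- to_concentration(series_from_curve(S), baseline = 1:8)
  expect_equal(as.numeric(conc$delta_r2), c_true, tolerance = 1e-10)
})

test_that("zero-baseline voxels are flagged invalid without an exception", {
  sig <- array(300, c(2, 1, 1, 20))
  sig[2, 1, 1, ] <- 0
  conc <- to_concentration(perfusion_series(sig, 45, 2000), baseline = 1:5)
  expect_true(conc$valid[1])
  expect_false(conc$valid[2])
})

test_that("series validation rejects bad TE and short series", {
  expect_error(perfusion_series(array(1, c(1, 1, 1, 45)), te_ms = 0,
                                tr_ms = 2000),
               class = "gliopred_protocol_error")
  expect_error(perfusion_series(array(1, c(1, 1, 1, 5)), 45, 2000),
               class = "gliopred_protocol_error")
})

test_that("bolus arrival is found within one frame on a clean injection", {
  tt <- (0:44) * 2
  t0 <- tt[12]
  c_true <- gamma_variate(tt, K = 0.3, t0 = t0, alpha = 3, beta = 3.5)
  set.seed(9)
  S <- 500 * exp(-0.045 * c_true) + rnorm(45, 0, 0.5)
  conc <- to_concentration(series_from_curve(S), baseline = 1:5)
  bol <- detect_bolus(conc)
  expect_true(abs(bol$arrival - 12) <= 2)
  expect_true(all(bol$baseline < bol$arrival))
})

test_that("flat noise-only series raises a no-bolus error", {
  set.seed(10)
  S <- 500 + rnorm(45, 0, 1)
  conc <- to_concentration(series_from_curve(S), baseline = 1:5)
  expect_error(detect_bolus(conc), class = "gliopred_no_bolus_error")
})

test_that("early bolus triggers a degraded-baseline warning", {
  tt <- (0:44) * 2
  c_true <- gamma_variate(tt, K = 0.5, t0 = tt[3], alpha = 3, beta = 3.5)
  S <- 500 * exp(-0.045 * c_true)
  conc <- to_concentration(series_from_curve(S), baseline = 1:2)
  expect_warning(detect_bolus(conc, min_baseline = 5),
                 class = "gliopred_degraded_baseline_warning")
})

test_that("noiseless gamma-variate samples are recovered to 1e-6 relative", {
  tt <- seq(0, 88, by = 2)
  truth <- c(K = 10, t0 = 20, alpha = 3, beta = 4)
  y <- gamma_variate(tt, truth["K"], truth["t0"], truth["alpha"],
                     truth["beta"])
  fit <- fit_gamma_variate(tt, y)
  expect_true(fit$converged)
  expect_equal(fit$K, unname(truth["K"]), tolerance = 1e-6)
  expect_equal(fit$t0, unname(truth["t0"]), tolerance = 1e-6)
  expect_equal(fit$alpha, unname(truth["alpha"]), tolerance = 1e-6)
  expect_equal(fit$beta, unname(truth["beta"]), tolerance = 1e-6)
  # analytic peak-time identity
  expect_equal(fit$peak_time, fit$t0 + fit$alpha * fit$beta, tolerance = 1e-9)
})

test_that("noisy replicate fits pin down the identifiable curve functionals", {
  # the raw amplitude K trades off exponentially with alpha through the
  # (t - t0)^alpha scale and is not identifiable at this noise level, so the
  # replicate contract is on the fitted curve's integral and peak time
  tt <- seq(0, 88, by = 2)
  truth <- c(K = 10, t0 = 20, alpha = 3, beta = 4)
  y0 <- gamma_variate(tt, truth["K"], truth["t0"], truth["alpha"],
                      truth["beta"])
  sigma <- 0.05 * max(y0)
  true_integral <- gamma_variate_integral(truth["K"], truth["alpha"],
                                          truth["beta"])
  true_peak_time <- truth["t0"] + truth["alpha"] * truth["beta"]
  set.seed(2024)
  stats <- t(replicate(100, {
    fit <- fit_gamma_variate(tt, y0 + rnorm(length(tt), 0, sigma))
    c(integ = gamma_variate_integral(fit$K, fit$alpha, fit$beta),
      pt = fit$peak_time)
  }))
  expect_true(all(abs(stats[, "integ"] - true_integral) /
                    true_integral < 0.10))
  expect_true(all(abs(stats[, "pt"] - true_peak_time) /
                    true_peak_time < 0.05))
})

test_that("leak-free voxels get K2 ~ 0 and an unchanged curve", {
  tt <- (0:44) * 2
  ref <- gamma_variate(tt, 0.2, 24, 3, 3.5)
  curves <- rbind(2.5 * ref, 0.7 * ref)
  out <- leakage_correct(curves, ref, time_s = tt)
  expect_lt(max(abs(out$k2)), 1e-6)
  expect_equal(out$corrected, curves, tolerance = 1e-9)
  expect_equal(out$k1, c(2.5, 0.7), tolerance = 1e-9)
})

test_that("a planted K2 is recovered and the leak-free component restored", {
  tt <- (0:44) * 2
  ref <- gamma_variate(tt, 0.2, 24, 3, 3.5)
  cum_ref <- c(0, cumsum((ref[-1] + ref[-45]) * diff(tt) / 2))
  k2_true <- 0.05
  leak_free <- 1.8 * ref
  measured <- leak_free - k2_true * cum_ref
  out <- leakage_correct(matrix(measured, 1), ref, time_s = tt)
  expect_equal(out$k2[1], k2_true, tolerance = 0.05 * k2_true)
  rms <- sqrt(mean((out$corrected[1, ] - leak_free)^2)) /
    sqrt(mean(leak_free^2))
  expect_lt(rms, 0.02)
})

test_that("an all-zero reference curve is a reference error", {
  expect_error(leakage_correct(matrix(1, 1, 45), rep(0, 45),
                               time_s = (0:44) * 2),
               class = "gliopred_reference_error")
})

test_that("trapezoidal CBV matches the closed-form gamma-variate integral", {
  K <- 8; alpha <- 2.5; beta <- 4; t0 <- 10
  tt <- seq(0, 150, by = beta / 20)
  y <- gamma_variate(tt, K, t0, alpha, beta)
  cbv <- compute_cbv(matrix(y, 1), time_s = tt)$cbv
  expect_equal(cbv, gamma_variate_integral(K, alpha, beta),
               tolerance = 0.01)
})

test_that("trapezoid error shrinks with the square of the step", {
  K <- 8; alpha <- 2.5; beta <- 4; t0 <- 10
  exact <- gamma_variate_integral(K, alpha, beta)
  err <- sapply(c(beta / 20, beta / 10, beta / 5), function(dt) {
    tt <- seq(0, 150, by = dt)
    abs(compute_cbv(matrix(gamma_variate(tt, K, t0, alpha, beta), 1),
                    time_s = tt)$cbv - exact)
  })
  expect_true(all(diff(err) > 0))           # monotone in dt
  expect_lt(err[1], err[2] / 2)             # ~ dt^2 scaling
})

test_that("CBV of a zero curve is zero and negatives clamp with a flag", {
  tt <- (0:44) * 2
  expect_equal(compute_cbv(matrix(0, 1, 45), time_s = tt)$cbv, 0)
  out <- compute_cbv(matrix(-1, 1, 45), time_s = tt)
  expect_equal(out$cbv, 0)
  expect_true(out$clamped)
})

test_that("CBV is linear in the curve and rCBV is scale-invariant", {
  tt <- (0:44) * 2
  y <- gamma_variate(tt, 0.2, 24, 3, 3.5)
  c1 <- compute_cbv(matrix(y, 1), time_s = tt)$cbv
  c3 <- compute_cbv(matrix(3 * y, 1), time_s = tt)$cbv
  expect_equal(c3, 3 * c1, tolerance = 1e-12)

  cbv <- c(1:10, 11)
  mask <- c(rep(TRUE, 10), FALSE)
  expect_equal(normalize_rcbv(cbv, mask)[11], 2)          # 11 / mean(1:10)
  expect_equal(normalize_rcbv(10 * cbv, mask),
               normalize_rcbv(cbv, mask), tolerance = 1e-12)
  expect_equal(mean(normalize_rcbv(cbv, mask)[mask]), 1)
})

test_that("rCBV normalization errors on empty or nonpositive references", {
  expect_error(normalize_rcbv(1:5, rep(FALSE, 5)),
               class = "gliopred_normalization_error")
  expect_error(normalize_rcbv(rep(0, 5), rep(TRUE, 5)),
               class = "gliopred_normalization_error")
  expect_error(compute_cbv(matrix(1, 1, 10), window = 5:12,
                           time_s = (0:9) * 2),
               class = "gliopred_validation_error")
})
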