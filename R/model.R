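#' Logistic predictive-probability model for treatment response
#'
#' Constructs the logistic regression model that scores a contrast-enhancing
#' lesion's probability of true progression (TP) from three imaging features:
#' the lesion median fractional anisotropy (FA), the median Westin linear
#' anisotropy coefficient (CL), and the lesion maximum relative cerebral blood
#' volume (rCBV_max, the 90th-percentile rCBV). The default coefficients are
#' those of the published model trained on glioblastoma patients treated with
#' surgery and chemoradiation; lesions are called TP when the predictive
#' probability (PP) is at or above the 50% threshold and pseudoprogression
#' (PsP) otherwise.
#'
#' `training_cutoff` records the operating point reported for the original
#' training cohort (0.55). It is metadata only: classification always uses
#' `threshold`, matching how the model is applied prospectively.
#'
#' @param beta0 Intercept.
#' @param beta1 Coefficient of median FA.
#' @param beta2 Coefficient of median CL.
#' @param beta3 Coefficient of rCBV_max.
#' @param threshold Classification threshold on the probability scale,
#'   strictly inside (0, 1). Default 0.5.
#' @param training_cutoff Historical training-cohort cutoff, stored as
#'   metadata and never used for classification.
#' @return An object of class `prediction_model`.
#' @examples
#' m <- prediction_model()
#' compute_pp(fa = 0.15, cl = 0.05, rcbv_max = 7.94, model = m)
#' @export
prediction_model <- function(beta0 = -16.17, beta1 = 194.01, beta2 = -285.65,
                             beta3 = 1.21, threshold = 0.5,
                             training_cutoff = 0.55) {
  for (nm in c("beta0", "beta1", "beta2", "beta3", "threshold")) {
    v <- get(nm)
    if (!is_scalar_number(v))
      stop_gliopred(sprintf("'%s' must be a single finite number", nm),
                    "gliopred_validation_error")
  }
  if (threshold <= 0 || threshold >= 1)
    stop_gliopred("'threshold' must lie strictly inside (0, 1)",
                  "gliopred_validation_error")
  structure(
    list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
         threshold = threshold, training_cutoff = training_cutoff),
    class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("Multiparametric MRI prediction model (logistic)\n")
  cat(sprintf("  PP = 1 / (1 + exp(-(%g + %g*FA + %g*CL + %g*rCBV_max)))\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  classification threshold: PP >= %.2f -> TP, else PsP\n",
              x$threshold))
  cat(sprintf("  training-cohort cutoff (metadata): %.2f\n", x$training_cutoff))
  invisible(x)
}

#' Compute the predictive probability of true progression
#'
#' Evaluates the logistic model
#' \deqn{PP = 1 / (1 + \exp(-(\beta_0 + \beta_1 FA + \beta_2 CL +
#'   \beta_3\, rCBV_{max})))}
#' for one or more lesions. The evaluation goes through [stats::plogis()], so
#' extreme linear predictors saturate to 0 or 1 without overflow.
#'
#' @param fa Median fractional anisotropy, in \[0, 1\].
#' @param cl Median Westin linear-anisotropy coefficient, non-negative.
#' @param rcbv_max Lesion 90th-percentile relative cerebral blood volume,
#'   non-negative.
#' @param model A [prediction_model()].
#' @return Numeric vector of probabilities in (0, 1) (0/1 only at saturation).
#' @examples
#' compute_pp(0.09, 0.03, 1.6)   # low PP, pseudoprogression regime
#' compute_pp(0.35, 0.14, 2.0)   # high PP, true progression regime
#' @export
compute_pp <- function(fa, cl, rcbv_max, model = prediction_model()) {
  stopifnot(inherits(model, "prediction_model"))
  for (nm in c("fa", "cl", "rcbv_max")) {
    v <- get(nm)
    if (is.null(v) || length(v) == 0L || anyNA(v))
      stop_gliopred(sprintf("required feature '%s' is missing", nm),
                    "gliopred_missing_feature_error")
    if (!is.numeric(v) || !all(is.finite(v)))
      stop_gliopred(sprintf("feature '%s' must be finite numeric", nm),
                    "gliopred_validation_error")
  }
  if (any(fa < 0 | fa > 1))
    stop_gliopred("'fa' must lie in [0, 1]", "gliopred_validation_error")
  if (any(cl < 0) || any(rcbv_max < 0))
    stop_gliopred("'cl' and 'rcbv_max' must be non-negative",
                  "gliopred_validation_error")
  lp <- model$beta0 + model$beta1 * fa + model$beta2 * cl +
    model$beta3 * rcbv_max
  stats::plogis(lp)
}

#' Classify a lesion as true progression or pseudoprogression
#'
#' Applies the 50% rule (or the model's configured threshold): a lesion is
#' true progression (TP) when PP >= threshold and pseudoprogression (PsP)
#' otherwise. The boundary PP == threshold is TP.
#'
#' @param pp Predictive probability, in \[0, 1\]; vectorized.
#' @param model A [prediction_model()] supplying the threshold.
#' @return Character vector of `"TP"` / `"PsP"`.
#' @examples
#' classify_response(c(0.99, 0.01, 0.5))
#' @export
classify_response <- function(pp, model = prediction_model()) {
  stopifnot(inherits(model, "prediction_model"))
  if (!is.numeric(pp) || length(pp) == 0L || anyNA(pp) || !all(is.finite(pp)))
    stop_gliopred("'pp' must be finite numeric", "gliopred_validation_error")
  if (any(pp < 0 | pp > 1))
    stop_gliopred("'pp' must lie in [0, 1]", "gliopred_validation_error")
  ifelse(pp >= model$threshold, "TP", "PsP")
}

#' Reference-standard label from histopathology
#'
#' Maps the percentage of malignant features in a re-resected specimen to the
#' histopathological reference label: more than 25% malignant features is
#' true progression, less than 25% is pseudoprogression. Exactly 25% is not
#' covered by either rule and returns `"indeterminate"`, flagging the case
#' for manual adjudication.
#'
#' @param percent_malignant Percentage of malignant features, in \[0, 100\];
#'   vectorized.
#' @return Character vector of `"TP"` / `"PsP"` / `"indeterminate"`.
#' @examples
#' label_from_histology(c(80, 5, 25))
#' @export
label_from_histology <- function(percent_malignant) {
  if (!is.numeric(percent_malignant) || length(percent_malignant) == 0L ||
      anyNA(percent_malignant) || !all(is.finite(percent_malignant)))
    stop_gliopred("'percent_malignant' must be finite numeric",
                  "gliopred_validation_error")
  if (any(percent_malignant < 0 | percent_malignant > 100))
    stop_gliopred("'percent_malignant' must lie in [0, 100]",
                  "gliopred_validation_error")
  ifelse(percent_malignant > 25, "TP",
         ifelse(percent_malignant < 25, "PsP", "indeterminate"))
}

#' Concordance between model calls and the reference standard
#'
#' Compares predicted TP/PsP labels against reference-standard labels
#' (histopathology or modified RANO) and reports overall and per-class
#' agreement.
#'
#' @param predicted Character vector of `"TP"` / `"PsP"` model calls.
#' @param reference Character vector of reference labels, same length; every
#'   element must be `"TP"` or `"PsP"` (no missing references).
#' @return A list with `n_total`, `n_concordant`, `rate`, and per-class
#'   agreement counts `n_tp_agree`, `n_psp_agree`.
#' @examples
#' concordance(c("TP", "PsP"), c("TP", "PsP"))
#' @export
concordance <- function(predicted, reference) {
  if (length(predicted) == 0L)
    stop_gliopred("concordance is undefined for an empty set of calls",
                  "gliopred_undefined_rate_error")
  if (length(predicted) != length(reference))
    stop_gliopred("'predicted' and 'reference' must have equal length",
                  "gliopred_validation_error")
  if (anyNA(reference) || !all(reference %in% c("TP", "PsP")))
    stop_gliopred("every call needs a reference label of 'TP' or 'PsP'",
                  "gliopred_validation_error")
  if (anyNA(predicted) || !all(predicted %in% c("TP", "PsP")))
    stop_gliopred("every predicted label must be 'TP' or 'PsP'",
                  "gliopred_validation_error")
  agree <- predicted == reference
  list(n_total = length(agree),
       n_concordant = sum(agree),
       rate = mean(agree),
       n_tp_agree = sum(agree & reference == "TP"),
       n_psp_agree = sum(agree & reference == "PsP"))
}

#' Format a predictive probability for reporting
#'
#' Renders PP as a percent string: nearest integer percent, except values
#' below 1% which are shown to one decimal place (e.g. `"0.1%"`), the
#' convention used in the clinical summary tables this package produces.
#'
#' @param pp Probability in \[0, 1\]; vectorized.
#' @return Character vector of formatted percentages.
#' @examples
#' format_pp_percent(c(0.9997, 0.0011, 0.787))
#' @export
format_pp_percent <- function(pp) {
  if (!is.numeric(pp) || anyNA(pp) || any(pp < 0 | pp > 1))
    stop_gliopred("'pp' must be numeric in [0, 1]", "gliopred_validation_error")
  pct <- 100 * pp
  ifelse(pct < 1, sprintf("%.1f%%", pct), sprintf("%.0f%%", pct))
}
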