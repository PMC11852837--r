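#' Sum of the products of diameters (SPD)
#'
#' Bidimensional tumor burden on post-contrast T1: for each target lesion the
#' longest in-plane diameter times its maximal perpendicular diameter, summed
#' over lesions.
#'
#' @param longest_cm Numeric vector of longest diameters (cm), one per
#'   lesion.
#' @param perpendicular_cm Maximal perpendicular diameters (cm), same
#'   length; each must not exceed the matching longest diameter.
#' @return SPD in cm^2.
#' @examples
#' spd(c(3, 1.5), c(2, 1))  # 7.5
#' @export
spd <- function(longest_cm, perpendicular_cm) {
  if (length(longest_cm) == 0L)
    stop_gliopred("at least one lesion measurement is required",
                  "gliopred_validation_error")
  if (length(longest_cm) != length(perpendicular_cm))
    stop_gliopred("diameter vectors must have equal length",
                  "gliopred_validation_error")
  ok <- is.numeric(longest_cm) && is.numeric(perpendicular_cm) &&
    all(is.finite(longest_cm)) && all(is.finite(perpendicular_cm))
  if (!ok || any(longest_cm <= 0) || any(perpendicular_cm <= 0))
    stop_gliopred("diameters must be positive finite numbers",
                  "gliopred_validation_error")
  if (any(perpendicular_cm > longest_cm))
    stop_gliopred("perpendicular diameter cannot exceed the longest diameter",
                  "gliopred_validation_error")
  sum(longest_cm * perpendicular_cm)
}

#' Classify response with modified RANO persistence rules
#'
#' Applied when no repeat surgery or biopsy is available. The lesion's SPD
#' timeline is compared against the scan at which the new lesion first
#' presented. A radiological change must persist for at least
#' `persist_weeks` weeks before it is called: the lesion is true progression
#' (TP) when SPD has increased by at least `progress_pct` percent at a
#' confirmation scan `persist_weeks` or more weeks after presentation, and
#' pseudoprogression (PsP) when SPD is stable or decreasing (increase below
#' `progress_pct` percent) at such a scan. With no confirmation scan at
#' least `persist_weeks` weeks out, the call is `"indeterminate"`.
#'
#' @param dates `Date` vector (or coercible) of scan dates, strictly
#'   increasing.
#' @param spd_cm2 SPD at each scan (cm^2, non-negative).
#' @param presentation Index of the initial-presentation scan of the new
#'   lesion. Default 1.
#' @param progress_pct Percent SPD increase defining progression.
#'   Default 25.
#' @param persist_weeks Minimum persistence interval in weeks. Default 4.
#' @return List with `label` (`"TP"`, `"PsP"` or `"indeterminate"`),
#'   `change_pct` at the deciding scan (NA when indeterminate), and
#'   `confirmation_date`.
#' @examples
#' classify_modified_rano(as.Date("2020-01-01") + c(0, 63),
#'                        c(4.0, 6.5))  # TP
#' @export
classify_modified_rano <- function(dates, spd_cm2, presentation = 1L,
                                   progress_pct = 25, persist_weeks = 4) {
  dates <- as.Date(dates)
  if (anyNA(dates) || is.unsorted(dates, strictly = TRUE))
    stop_gliopred("scan dates must be strictly increasing",
                  "gliopred_validation_error")
  if (length(dates) != length(spd_cm2) || anyNA(spd_cm2) || any(spd_cm2 < 0))
    stop_gliopred("one non-negative SPD per scan date is required",
                  "gliopred_validation_error")
  presentation <- as.integer(presentation)
  if (presentation < 1L || presentation > length(dates))
    stop_gliopred("'presentation' must index one of the scans",
                  "gliopred_validation_error")
  if (length(dates) < presentation + 1L)
    stop_gliopred("at least one follow-up scan after presentation is required",
                  "gliopred_validation_error")

  base_spd <- spd_cm2[presentation]
  weeks_out <- as.numeric(dates - dates[presentation]) / 7
  confirm <- which(seq_along(dates) > presentation &
                     weeks_out >= persist_weeks)
  if (length(confirm) == 0L)
    return(list(label = "indeterminate", change_pct = NA_real_,
                confirmation_date = as.Date(NA)))

  deciding <- max(confirm)  # latest confirmed observation decides
  change_pct <- if (base_spd > 0)
    100 * (spd_cm2[deciding] - base_spd) / base_spd
  else if (spd_cm2[deciding] > 0) Inf else 0
  label <- if (change_pct >= progress_pct) "TP" else "PsP"
  list(label = label, change_pct = change_pct,
       confirmation_date = dates[deciding])
}

#' Read a RANO measurement table and classify each lesion
#'
#' Convenience wrapper over [spd()] and [classify_modified_rano()] for a CSV
#' with columns `lesion_id`, `date` (ISO-8601), `longest_cm`,
#' `perpendicular_cm`. Rows sharing a `lesion_id` and `date` are treated as
#' multiple target lesions of one scan and their diameter products summed.
#'
#' @param measurements `data.frame` with the columns above, or a CSV path.
#' @param ... Passed to [classify_modified_rano()].
#' @return `data.frame` with one row per lesion_id: `label`, `change_pct`,
#'   `n_scans`.
#' @export
rano_from_table <- function(measurements, ...) {
  if (is.character(measurements))
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  need <- c("lesion_id", "date", "longest_cm", "perpendicular_cm")
  miss <- setdiff(need, names(measurements))
  if (length(miss) > 0L)
    stop_gliopred(paste0("RANO table is missing column(s): ",
                         paste(miss, collapse = ", ")),
                  "gliopred_input_error")
  out <- lapply(split(measurements, measurements$lesion_id), function(df) {
    by_date <- split(df, df$date)
    dts <- as.Date(names(by_date))
    o <- order(dts)
    spds <- vapply(by_date, function(x)
      spd(x$longest_cm, x$perpendicular_cm), numeric(1))[o]
    res <- classify_modified_rano(dts[o], spds, ...)
    data.frame(lesion_id = df$lesion_id[1L], label = res$label,
               change_pct = res$change_pct, n_scans = length(dts),
               stringsAsFactors = FALSE)
  })
  rownames_reset <- do.call(rbind, out)
  rownames(rownames_reset) <- NULL
  rownames_reset
}
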