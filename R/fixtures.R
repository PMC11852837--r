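#' Packaged per-lesion feature table of the six-patient case series
#'
#' Six long-term glioblastoma survivors with a new contrast-enhancing lesion
#' after chemoradiation: the lesion median FA, median CL and rCBV_max, the
#' predictive probability printed in the clinical summary, and the
#' reference-standard label (histopathology for patients 1-4, modified RANO
#' for patients 5-6). These are the published summary values transcribed
#' verbatim; `pp_printed_pct` is display metadata, not a model output.
#'
#' @return `data.frame` with columns `lesion_id`, `fa_median`, `cl_median`,
#'   `rcbv_max`, `pp_printed_pct`, `reference_label`, `reference_source`.
#' @examples
#' table2_features()
#' @export
table2_features <- function() {
  utils::read.csv(system.file("extdata", "lesion_features.csv",
                              package = "gliopred"),
                  stringsAsFactors = FALSE,
                  colClasses = c(lesion_id = "character"))
}

#' Packaged cohort table of the six long-term survivors
#'
#' Demographic, functional and molecular characteristics: gender, age at
#' diagnosis, Karnofsky performance status (recorded range), extent of
#' resection, MGMT promoter methylation status, completion of
#' standard-of-care chemoradiation, additional therapy, and overall survival
#' in years.
#'
#' @return `data.frame` with one row per patient.
#' @examples
#' cohort <- table1_cohort()
#' sum(cohort$mgmt_methylated)   # 5 of 6 methylated
#' range(cohort$os_years)        # 5.1 to 12.3 years
#' @export
table1_cohort <- function() {
  utils::read.csv(system.file("extdata", "cohort.csv", package = "gliopred"),
                  stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character",
                                 gender = "character", kps = "character"))
}

#' Checksums of the packaged fixture tables
#'
#' MD5 digests of the shipped CSV fixtures, so that any edit to the
#' transcribed values is detectable.
#'
#' @return Named character vector of MD5 hex digests.
#' @export
fixture_checksums <- function() {
  files <- c(lesion_features = system.file("extdata", "lesion_features.csv",
                                           package = "gliopred"),
             cohort = system.file("extdata", "cohort.csv",
                                  package = "gliopred"))
  sums <- tools::md5sum(files)
  names(sums) <- names(files)
  sums
}
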