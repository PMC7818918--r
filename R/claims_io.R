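# Loaders for the four input tables. All are delimited text (comma or tab,
# auto-detected from the header line), one row per record:
#
#   claims:     patient_id, dispense_date, generic_name, dosage_quantity,
#               period_field
#   diagnoses:  patient_id, date, icd10_code
#   procedures: patient_id, date, is_glaucoma_surgery_or_laser
#   covariates: patient_id plus any covariate columns (hba1c_percent, if
#               present, must lie in [3, 20])
#
# Dates must parse as ISO-8601 calendar dates. See inst/extdata for a worked
# example of each table.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0L) "\t" else ","
}

read_delim_auto <- function(path) {
  utils::read.table(path, sep = detect_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    comment.char = "", quote = "\"")
}

require_columns <- function(d, need, what) {
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(what, " table is missing columns: ", paste(miss, collapse = ", "))
}

parse_date_col <- function(x, what) {
  d <- as.Date(x, format = "%Y-%m-%d")
  if (anyNA(d) && !all(is.na(x) == is.na(d)))
    stop("unparseable dates in ", what, " (expected YYYY-MM-DD)")
  d
}

#' Attach dictionary information to a raw claims table
#'
#' Validates a claims data.frame (as read from file or produced by
#' [generate_claims_data()]), rejects rows with non-positive dosage with a
#' warning, resolves every generic name against the dictionary (unresolvable
#' names are a hard error) and returns the table sorted by patient and
#' dispense date with the dictionary columns joined on.
#'
#' @param claims data.frame with columns `patient_id`, `dispense_date`,
#'   `generic_name`, `dosage_quantity` (mL) and optionally `period_field`.
#' @param dictionary A drug dictionary data.frame.
#' @return The sorted, annotated claims data.frame.
#' @export
claims_from_frame <- function(claims, dictionary = drug_dictionary()) {
  require_columns(claims, c("patient_id", "dispense_date", "generic_name",
                            "dosage_quantity"), "claims")
  if (!inherits(claims$dispense_date, "Date"))
    claims$dispense_date <- parse_date_col(claims$dispense_date, "claims")
  bad <- !is.finite(claims$dosage_quantity) | claims$dosage_quantity <= 0
  if (any(bad)) {
    warning(sum(bad), " claim row(s) rejected: non-positive dosage_quantity")
    claims <- claims[!bad, , drop = FALSE]
  }
  e <- resolve_drug(claims$generic_name, dictionary)
  claims$class1 <- e$class1
  claims$class2 <- e$class2
  claims$is_fixed_combination <- e$is_fixed_combination
  claims$unit_bottle_volume <- e$unit_bottle_volume
  claims$dosing_frequency <- e$dosing_frequency
  claims <- claims[order(claims$patient_id, claims$dispense_date,
                         claims$generic_name), , drop = FALSE]
  rownames(claims) <- NULL
  claims
}

#' Load a prescription-claims table from a delimited text file
#'
#' @param path Path to the file.
#' @param dictionary A drug dictionary data.frame.
#' @return See [claims_from_frame()].
#' @export
load_claims <- function(path, dictionary = drug_dictionary()) {
  claims_from_frame(read_delim_auto(path), dictionary)
}

normalize_icd10 <- function(x) {
  substr(toupper(gsub("[. ]", "", x)), 1L, 4L)
}

#' Load a diagnosis table
#'
#' ICD-10 codes are normalized to their 4-character uppercase form
#' ("H40.1" -> "H401"). Codes unrelated to glaucoma are retained; the cohort
#' filter simply ignores them.
#'
#' @param path Path to the file.
#' @return data.frame with `patient_id`, `date`, `icd10_code`.
#' @export
load_diagnoses <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("patient_id", "date", "icd10_code"), "diagnosis")
  d$date <- parse_date_col(d$date, "diagnoses")
  d$icd10_code <- normalize_icd10(d$icd10_code)
  d
}

#' Load a procedure table
#'
#' @param path Path to the file.
#' @return data.frame with `patient_id`, `date`,
#'   `is_glaucoma_surgery_or_laser` (logical). Only `TRUE` rows matter
#'   downstream.
#' @export
load_procedures <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, c("patient_id", "date", "is_glaucoma_surgery_or_laser"),
                  "procedure")
  d$date <- parse_date_col(d$date, "procedures")
  d$is_glaucoma_surgery_or_laser <- as.logical(d$is_glaucoma_surgery_or_laser)
  d
}

#' Load a patient-covariate table
#'
#' Missing values are preserved (health-checkup variables are typically
#' observed for only a subset of patients). HbA1c values outside the
#' plausible NGSP range of 3-20% are set to missing with a warning.
#'
#' @param path Path to the file.
#' @return data.frame keyed by `patient_id`.
#' @export
load_covariates <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, "patient_id", "covariate")
  if ("hba1c_percent" %in% names(d)) {
    bad <- !is.na(d$hba1c_percent) & (d$hba1c_percent < 3 | d$hba1c_percent > 20)
    if (any(bad)) {
      warning(sum(bad), " hba1c_percent value(s) outside [3, 20] set to NA")
      d$hba1c_percent[bad] <- NA_real_
    }
  }
  d
}
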