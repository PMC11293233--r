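#' Cohort CSV schema
#'
#' Column names and types of the cohort file: one row per ICU stay, times
#' in minutes from ICU admission, follow-up in days, booleans written as
#' 0/1, decimal separator ".". `pe_dx_hours` is the time from ICU
#' admission to the PE diagnosis in hours.
#'
#' @return Named character vector mapping column name to storage type
#'   (`"character"`, `"integer"`, `"numeric"` or `"logical"`).
#' @export
cohort_schema <- function() {
  c(patient_id = "character",
    age = "integer",
    male = "logical",
    hx_heart_failure = "logical",
    hx_chronic_lung_disease = "logical",
    hx_chronic_cardiopulmonary = "logical",
    hx_cancer = "logical",
    heart_rate_worst = "numeric",
    sbp_worst = "numeric",
    temp_worst = "numeric",
    resp_rate_worst = "numeric",
    sao2_worst = "numeric",
    altered_mental_status = "logical",
    intubated = "logical",
    vasoactive_infusion = "logical",
    apache_iv = "integer",
    died_in_hospital = "logical",
    followup_days = "numeric",
    admission_dx = "character",
    pe_dx_hours = "numeric")
}

# Fields whose absence means the stay cannot be analysed ("key data"):
# sex, severity score, outcome and follow-up, admission diagnosis, age and
# all five worst-case vitals. Unrecorded comorbidity/treatment flags are
# read as FALSE (uncoded history), never as missing.
key_fields <- function() {
  c("male", "apache_iv", "died_in_hospital", "followup_days",
    "admission_dx", "age", "heart_rate_worst", "sbp_worst", "temp_worst",
    "resp_rate_worst", "sao2_worst")
}

default_flag_fields <- function() {
  c("hx_heart_failure", "hx_chronic_lung_disease",
    "hx_chronic_cardiopulmonary", "hx_cancer", "altered_mental_status",
    "intubated", "vasoactive_infusion")
}

parse_logical_col <- function(x, col, path) {
  x <- trimws(x)
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "T")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F")] <- FALSE
  bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as 0/1 in column '%s', row %d of %s",
                 x[bad[1]], col, bad[1], path), call. = FALSE)
  }
  out
}

parse_numeric_col <- function(x, col, path, integer = FALSE) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | x == "NA"
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!miss & is.na(out))
  if (length(bad)) {
    stop(sprintf("cannot parse '%s' as a number in column '%s', row %d of %s",
                 x[bad[1]], col, bad[1], path), call. = FALSE)
  }
  if (integer) out <- as.integer(round(out))
  out
}

#' Read a patient cohort from CSV
#'
#' Reads one `PatientRecord` per row using the schema of
#' [cohort_schema()]. In strict mode, rows missing any key field (sex,
#' APACHE-IV, outcome, follow-up, admission diagnosis, age or a worst-case
#' vital) are moved to an exclusion report with reason
#' `"missing key data"` instead of being dropped silently. Missing
#' comorbidity and treatment flags default to `FALSE`.
#'
#' @param path Path to a cohort CSV file.
#' @param strict Logical; exclude rows with missing key data (default
#'   `TRUE`). When `FALSE`, such rows are kept with `NA`s.
#' @return A list with components `records` (data frame of retained
#'   records) and `excluded` (data frame with columns `patient_id`,
#'   `reason`). Retained plus excluded rows partition the input.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  schema <- cohort_schema()
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "NA")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols)) {
    stop("malformed cohort header, missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[names(schema)]
  rec <- raw
  for (col in names(schema)) {
    rec[[col]] <- switch(schema[[col]],
      character = as.character(raw[[col]]),
      integer   = parse_numeric_col(raw[[col]], col, path, integer = TRUE),
      numeric   = parse_numeric_col(raw[[col]], col, path),
      logical   = parse_logical_col(raw[[col]], col, path))
  }
  for (col in default_flag_fields()) {
    rec[[col]][is.na(rec[[col]])] <- FALSE
  }
  rec$admission_dx[!is.na(rec$admission_dx) &
                     trimws(rec$admission_dx) == ""] <- NA_character_
  excluded <- data.frame(patient_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  if (strict && nrow(rec)) {
    miss <- !complete.cases(rec[key_fields()])
    if (any(miss)) {
      excluded <- data.frame(patient_id = rec$patient_id[miss],
                             reason = "missing key data",
                             stringsAsFactors = FALSE)
      rec <- rec[!miss, , drop = FALSE]
    }
  }
  rownames(rec) <- NULL
  validate_cohort(rec)
  list(records = rec, excluded = excluded)
}

#' Validate cohort record invariants
#'
#' Checks range invariants on a cohort data frame: `age >= 0`,
#' `sao2_worst` in \[0, 100\], `sbp_worst > 0`, `followup_days >= 0`.
#' `NA`s (possible in non-strict reads) are ignored.
#'
#' @param records Cohort data frame.
#' @return Invisibly `TRUE`; stops on the first violated invariant.
#' @export
validate_cohort <- function(records) {
  chk <- function(ok, what) {
    bad <- which(!ok)
    if (length(bad)) {
      stop(sprintf("invalid record (patient_id %s): %s",
                   records$patient_id[bad[1]], what), call. = FALSE)
    }
  }
  ok_na <- function(x, test) is.na(x) | test
  chk(ok_na(records$age, records$age >= 0), "age < 0")
  chk(ok_na(records$sao2_worst,
            records$sao2_worst >= 0 & records$sao2_worst <= 100),
      "sao2_worst outside [0, 100]")
  chk(ok_na(records$sbp_worst, records$sbp_worst > 0), "sbp_worst <= 0")
  chk(ok_na(records$followup_days, records$followup_days >= 0),
      "followup_days < 0")
  invisible(TRUE)
}

#' Write a patient cohort to CSV
#'
#' Writes records in the documented column order with booleans encoded as
#' 0/1. `read_cohort(write_cohort(x))` round-trips valid records
#' losslessly.
#'
#' @param records Cohort data frame (see [cohort_schema()]).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_cohort <- function(records, path) {
  schema <- cohort_schema()
  missing_cols <- setdiff(names(schema), names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_cohort(records)
  out <- records[names(schema)]
  for (col in names(schema)[schema == "logical"]) {
    out[[col]] <- as.integer(out[[col]])
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Write an exclusion report
#'
#' @param excluded Data frame with columns `patient_id` and `reason`.
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @export
write_exclusions <- function(excluded, path) {
  stopifnot(all(c("patient_id", "reason") %in% names(excluded)))
  if (nrow(excluded) && any(!nzchar(excluded$reason))) {
    stop("every exclusion needs a non-empty reason", call. = FALSE)
  }
  write.csv(excluded[c("patient_id", "reason")], path, row.names = FALSE)
  invisible(path)
}
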