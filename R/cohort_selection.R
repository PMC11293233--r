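#' Default blocklist of admission diagnoses suggestive of primary PE
#'
#' Admission-diagnosis phrases indicating that the PE was the reason for
#' ICU admission rather than a complication of another critical illness.
#' Matching is case-insensitive substring matching; the list is
#' configurable because it is an illustrative, not exhaustive, set.
#'
#' @return Character vector of seven phrases.
#' @export
default_dx_blocklist <- function() {
  c("thrombus, arterial",
    "thrombectomy",
    "embolectomy",
    "thrombosis, vascular (deep vein)",
    "chest pain, atypical (noncardiac chest pain)",
    "chest pain, respiratory",
    "vena cava filter insertion")
}

#' Default diagnosis-text pattern identifying pulmonary embolism
#'
#' Case-insensitive regular expression matching PE entries in a
#' free-text diagnosis list, covering both "pulmonary embolism" and
#' inverted forms such as "embolus, pulmonary".
#'
#' @return A single regular expression string.
#' @export
default_pe_pattern <- function() {
  "(pulmonary.*embol)|(embol.*pulmonary)"
}

#' Select patients with secondary PE
#'
#' A patient qualifies when a PE entry appears on the running diagnosis
#' list with a timestamp in `(0, window_hours]` hours after ICU admission
#' and that entry is not itself the primary admission diagnosis. A PE
#' entry timestamped exactly at admission (0 minutes) is treated as
#' present on admission -- i.e. primary PE -- and does not qualify.
#'
#' @param diagnoses Data frame with columns `patient_id`, `dx_text`,
#'   `minutes_from_admission`, `is_primary_admission_dx`.
#' @param window_hours Inclusion window in hours after admission
#'   (default 48).
#' @param pe_pattern Case-insensitive regex identifying PE entries
#'   (default [default_pe_pattern()]).
#' @return Character vector of qualifying `patient_id`s (sorted, unique).
#'   The result is monotone in `window_hours`: a larger window yields a
#'   superset.
#' @export
select_secondary_pe <- function(diagnoses, window_hours = 48,
                                pe_pattern = default_pe_pattern()) {
  stopifnot(window_hours > 0)
  need <- c("patient_id", "dx_text", "minutes_from_admission",
            "is_primary_admission_dx")
  missing_cols <- setdiff(need, names(diagnoses))
  if (length(missing_cols)) {
    stop("diagnosis table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  is_pe <- grepl(pe_pattern, diagnoses$dx_text, ignore.case = TRUE)
  in_window <- diagnoses$minutes_from_admission > 0 &
    diagnoses$minutes_from_admission <= window_hours * 60
  ok <- is_pe & in_window & !diagnoses$is_primary_admission_dx
  sort(unique(diagnoses$patient_id[ok]))
}

#' Exclude records with an admission diagnosis suggestive of primary PE
#'
#' Records whose `admission_dx` contains any blocklist phrase
#' (case-insensitive substring match) are moved to an exclusion report
#' with reason `"primary PE admission diagnosis"`. Kept and excluded
#' records partition the input.
#'
#' @param records Cohort data frame.
#' @param blocklist Non-empty character vector of phrases (default
#'   [default_dx_blocklist()]).
#' @return List with components `kept` (data frame) and `excluded` (data
#'   frame with `patient_id`, `reason`).
#' @export
exclude_primary_pe_dx <- function(records, blocklist = default_dx_blocklist()) {
  if (!length(blocklist)) stop("blocklist must be non-empty", call. = FALSE)
  dx <- tolower(records$admission_dx)
  hit <- rep(FALSE, nrow(records))
  for (phrase in tolower(blocklist)) {
    hit <- hit | grepl(phrase, dx, fixed = TRUE)
  }
  hit[is.na(hit)] <- FALSE
  kept <- records[!hit, , drop = FALSE]
  rownames(kept) <- NULL
  excluded <- data.frame(
    patient_id = records$patient_id[hit],
    reason = rep("primary PE admission diagnosis", sum(hit)),
    stringsAsFactors = FALSE)
  list(kept = kept, excluded = excluded)
}
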