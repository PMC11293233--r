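require_vitals <- function(p) {
  vit <- c(heart_rate_worst = "heart_rate", sbp_worst = "sbp",
           temp_worst = "temperature", resp_rate_worst = "resp_rate",
           sao2_worst = "sao2")
  for (col in names(vit)) {
    if (any(is.na(p[[col]]))) {
      stop("missing worst-case vital: ", vit[[col]], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' PESI score
#'
#' Pulmonary Embolism Severity Index: one point per year of age, plus
#' 10 points each for male sex, history of heart failure and history of
#' chronic lung disease; 20 points each for heart rate >= 110/min,
#' respiratory rate >= 30/min, temperature < 36.0 C and oxygen saturation
#' < 90%; 30 points each for history of cancer and systolic blood
#' pressure < 100 mmHg; and 60 points for altered mental status. Vitals
#' are the per-patient worst-case values (see [most_aberrant()]). Age
#' contributes `floor(age)` points (integer years).
#'
#' @param p Cohort data frame (one or more records).
#' @return Integer vector of PESI scores; minimum possible score is the
#'   patient's age.
#' @references Aujesky et al., Am J Respir Crit Care Med 2005 (original
#'   derivation of the index).
#' @export
pesi_score <- function(p) {
  if (any(is.na(p$age)) || any(p$age < 0)) {
    stop("age must be a non-negative number", call. = FALSE)
  }
  require_vitals(p)
  as.integer(floor(p$age) +
    10L * (p$male + p$hx_heart_failure + p$hx_chronic_lung_disease) +
    20L * ((p$heart_rate_worst >= 110) + (p$resp_rate_worst >= 30) +
           (p$temp_worst < 36.0) + (p$sao2_worst < 90)) +
    30L * (p$hx_cancer + (p$sbp_worst < 100)) +
    60L * p$altered_mental_status)
}

#' PESI risk class
#'
#' Maps a PESI score to the five published risk strata: <= 65 class I,
#' 66-85 class II, 86-105 class III, 106-125 class IV, > 125 class V.
#'
#' @param score Integer vector of PESI scores (>= 0).
#' @return Ordered factor with levels `I` to `V`.
#' @export
pesi_class <- function(score) {
  if (any(is.na(score)) || any(score < 0)) {
    stop("PESI score must be non-negative", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 65, 85, 105, 125, Inf),
      labels = c("I", "II", "III", "IV", "V"), ordered_result = TRUE)
}

#' sPESI score
#'
#' Simplified PESI: one point each (maximum 6) for age strictly greater
#' than 80 years, history of cancer, chronic cardiopulmonary disease,
#' heart rate >= 110/min, systolic blood pressure < 100 mmHg and oxygen
#' saturation < 90%.
#'
#' @inheritParams pesi_score
#' @return Integer vector in \[0, 6\].
#' @export
spesi_score <- function(p) {
  if (any(is.na(p$age)) || any(p$age < 0)) {
    stop("age must be a non-negative number", call. = FALSE)
  }
  require_vitals(p)
  as.integer((p$age > 80) + p$hx_cancer + p$hx_chronic_cardiopulmonary +
    (p$heart_rate_worst >= 110) + (p$sbp_worst < 100) +
    (p$sao2_worst < 90))
}

#' ICU-sPESI score
#'
#' sPESI extended with three equally weighted severity markers (maximum
#' 9): intubation, altered mental status and vasoactive drug infusion.
#'
#' @inheritParams pesi_score
#' @return Integer vector in \[0, 9\], always `>= spesi_score(p)` and at
#'   most 3 points above it.
#' @export
icu_spesi_score <- function(p) {
  as.integer(spesi_score(p) + p$intubated + p$altered_mental_status +
    p$vasoactive_infusion)
}

#' ICU-sPESI risk class
#'
#' Maps an ICU-sPESI score to its four risk classes: <= 2 points class I
#' (low risk), 3-4 class II (intermediate), 5-6 class III (high),
#' >= 7 class IV (very high).
#'
#' @param score Integer vector of ICU-sPESI scores in \[0, 9\].
#' @return Ordered factor with levels `I` to `IV`.
#' @export
icu_spesi_class <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 9)) {
    stop("ICU-sPESI score must lie in [0, 9]", call. = FALSE)
  }
  cut(score, breaks = c(-Inf, 2, 4, 6, Inf),
      labels = c("I", "II", "III", "IV"), ordered_result = TRUE)
}

#' Score panel for a cohort
#'
#' Computes all four scores and both risk classes per patient: PESI with
#' its class, sPESI, ICU-sPESI with its class, and the APACHE-IV score
#' passed through unchanged (APACHE-IV is precomputed in the source
#' database and consumed as given).
#'
#' @param p Cohort data frame with complete records.
#' @return Data frame with columns `patient_id`, `pesi`, `pesi_class`,
#'   `spesi`, `icu_spesi`, `icu_spesi_class`, `apache_iv`.
#' @export
score_panel <- function(p) {
  pesi <- pesi_score(p)
  spesi <- spesi_score(p)
  icu <- icu_spesi_score(p)
  if (any(is.na(p$apache_iv)) || any(p$apache_iv < 0)) {
    stop("apache_iv must be a non-negative score", call. = FALSE)
  }
  data.frame(patient_id = p$patient_id,
             pesi = pesi,
             pesi_class = pesi_class(pesi),
             spesi = spesi,
             icu_spesi = icu,
             icu_spesi_class = icu_spesi_class(icu),
             apache_iv = as.integer(p$apache_iv),
             stringsAsFactors = FALSE)
}
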