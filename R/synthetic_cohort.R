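#' Default criterion prevalences for the synthetic cohort
#'
#' Marginal prevalences of the binary score criteria, anchored to the
#' composition of a published secondary-PE ICU cohort: male sex 50.6%,
#' heart failure 16.9%, chronic lung disease 28.6%, cancer 22.8%, heart
#' rate >= 110 33.4%, SBP < 100 54.2%, temperature < 36.0 8.0%,
#' respiratory rate >= 30 23.0%, SaO2 < 90 16.5%, altered mental status
#' 40.4%, intubation 36.5%, vasoactive infusion 19.5%. `cp_extra` is a
#' top-up component so that chronic cardiopulmonary disease (the union of
#' heart failure, chronic lung disease and the top-up) lands near 42.7%.
#'
#' @return Named numeric vector of probabilities.
#' @export
default_prevalences <- function() {
  c(male = 0.506,
    hx_heart_failure = 0.169,
    hx_chronic_lung_disease = 0.286,
    hx_cancer = 0.228,
    cp_extra = 0.034,
    hr_high = 0.334,
    sbp_low = 0.542,
    temp_low = 0.080,
    rr_high = 0.230,
    sao2_low = 0.165,
    altered_mental_status = 0.404,
    intubated = 0.365,
    vasoactive_infusion = 0.195)
}

#' Default latent-severity loadings
#'
#' Loading of each binary criterion on the single Gaussian latent
#' severity factor. Acute markers (abnormal vitals, altered mental
#' status, intubation, vasoactive support) load strongly; chronic
#' comorbidities load weakly; sex is nearly independent of severity.
#'
#' @return Named numeric vector in \[0, 1\], same names as
#'   [default_prevalences()].
#' @export
default_loadings <- function() {
  c(male = 0.05,
    hx_heart_failure = 0.25,
    hx_chronic_lung_disease = 0.25,
    hx_cancer = 0.20,
    cp_extra = 0.25,
    hr_high = 0.60,
    sbp_low = 0.60,
    temp_low = 0.60,
    rr_high = 0.60,
    sao2_low = 0.60,
    altered_mental_status = 0.60,
    intubated = 0.60,
    vasoactive_infusion = 0.60)
}

#' Default class-conditional in-hospital mortality
#'
#' In-hospital death probability by ICU-sPESI risk class, anchored to
#' observed class-specific mortality in a secondary-PE ICU cohort:
#' 8.4% (class I), 19.1% (II), 39.4% (III), 73.3% (IV).
#'
#' @return Named numeric vector.
#' @export
default_class_mortality <- function() {
  c(I = 0.084, II = 0.191, III = 0.394, IV = 0.733)
}

#' Specification of a synthetic secondary-PE ICU cohort
#'
#' Bundles every parameter of the generator. A single Gaussian latent
#' severity factor induces positive dependence among the binary criteria
#' (threshold model), drives the APACHE-IV benchmark score, and adds a
#' within-class severity gradient to mortality so that a well-calibrated
#' general severity score can out-discriminate the PE-specific scores.
#'
#' @param n_patients Number of genuine secondary-PE stays (default 812).
#' @param n_decoys Number of extra stays that the cohort-selection stage
#'   must reject (alternating late-PE and primary-PE decoys; default 0).
#' @param prevalences Named probabilities, see [default_prevalences()].
#' @param loadings Named loadings in \[0, 1\], see [default_loadings()].
#' @param class_mortality Death probability per ICU-sPESI class, see
#'   [default_class_mortality()].
#' @param severity_slope Residual within-class log-odds of death per
#'   latent-severity SD (default 1.0). The per-class mean death
#'   probability is re-anchored to `class_mortality` exactly, so this
#'   adds discrimination without moving class-level mortality.
#' @param apache_median,apache_slope,apache_noise_sd Log-scale model for
#'   APACHE-IV: `round(exp(log(median) + slope * L + noise))` with
#'   latent severity `L` (defaults 56, 0.45, 0.20 -- marginal median 56,
#'   IQR roughly 40-78).
#' @param age_mean,age_sd,age_min,age_max Truncated-normal age model in
#'   years (defaults 66, 15, 18, 99; median 66, IQR roughly 56-76).
#'   Age is independent of the latent severity.
#' @param death_time_median_days Median of the log-normal in-hospital
#'   death-time distribution in days (default 6.2).
#' @param death_time_sdlog Log-SD of the death-time distribution
#'   (default 1.4).
#' @param censor_days Administrative censoring time for survivors in
#'   days (default 55).
#' @param seed Integer seed governing all randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 812,
                        n_decoys = 0,
                        prevalences = default_prevalences(),
                        loadings = default_loadings(),
                        class_mortality = default_class_mortality(),
                        severity_slope = 1.0,
                        apache_median = 56,
                        apache_slope = 0.45,
                        apache_noise_sd = 0.20,
                        age_mean = 66, age_sd = 15,
                        age_min = 18, age_max = 99,
                        death_time_median_days = 6.2,
                        death_time_sdlog = 1.4,
                        censor_days = 55,
                        seed = 1L) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (n_decoys < 0) stop("n_decoys must be >= 0", call. = FALSE)
  missing_names <- setdiff(names(default_prevalences()), names(prevalences))
  if (length(missing_names)) {
    stop("prevalences is missing: ", paste(missing_names, collapse = ", "),
         call. = FALSE)
  }
  if (any(prevalences < 0 | prevalences > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(class_mortality < 0 | class_mortality > 1)) {
    stop("class_mortality must lie in [0, 1]", call. = FALSE)
  }
  if (any(loadings < 0 | loadings >= 1)) {
    stop("loadings must lie in [0, 1)", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_decoys = as.integer(n_decoys),
                 prevalences = prevalences,
                 loadings = loadings,
                 class_mortality = class_mortality,
                 severity_slope = severity_slope,
                 apache_median = apache_median,
                 apache_slope = apache_slope,
                 apache_noise_sd = apache_noise_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, age_max = age_max,
                 death_time_median_days = death_time_median_days,
                 death_time_sdlog = death_time_sdlog,
                 censor_days = censor_days,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Per-channel value ranges used when emitting raw vitals. "worst" ranges
# sit strictly on the triggering (flag = TRUE) or safe (flag = FALSE)
# side of each score cut-off; "base" ranges are strictly less aberrant
# than either worst range so that the injected worst window is the
# most aberrant window median.
vitals_value_ranges <- function() {
  list(
    heart_rate  = list(flag = c(112, 150), calm = c(95, 108),
                       base = c(70, 93), digits = 0),
    resp_rate   = list(flag = c(30, 44), calm = c(18, 28),
                       base = c(12, 17), digits = 0),
    sbp         = list(flag = c(72, 99), calm = c(101, 112),
                       base = c(114, 140), digits = 0),
    temperature = list(flag = c(34.0, 35.8), calm = c(36.1, 36.4),
                       base = c(36.6, 37.9), digits = 1),
    sao2        = list(flag = c(75, 89.4), calm = c(90.1, 96.4),
                       base = c(96.6, 100), digits = 1))
}

runif_between <- function(lo, hi) lo + runif(length(lo)) * (hi - lo)

# Solve, per risk class, the intercept c such that
# mean(plogis(c + slope * L)) over class members equals the target rate,
# so the class-level mortality parameter is preserved exactly while the
# latent severity retains within-class prognostic value.
class_anchored_death_prob <- function(L, cls, class_mortality, slope) {
  p <- numeric(length(L))
  for (lev in levels(cls)) {
    idx <- which(cls == lev)
    if (!length(idx)) next
    target <- unname(class_mortality[[lev]])
    if (target <= 0) {
      p[idx] <- 0
    } else if (target >= 1) {
      p[idx] <- 1
    } else if (slope == 0) {
      p[idx] <- target
    } else {
      f <- function(c0) mean(plogis(c0 + slope * L[idx])) - target
      c0 <- uniroot(f, c(-40, 40), tol = 1e-10)$root
      p[idx] <- plogis(c0 + slope * L[idx])
    }
  }
  p
}

#' Generate a synthetic secondary-PE ICU cohort
#'
#' Draws a cohort with the statistical structure the validation pipeline
#' assumes: positively dependent binary criteria via a single Gaussian
#' latent severity factor (threshold model), worst-case vitals consistent
#' with the realized threshold flags, an APACHE-IV benchmark driven by
#' the same latent factor, in-hospital death drawn with class-anchored
#' probability (per ICU-sPESI class, with a residual within-class
#' severity gradient), log-normal death times, and administrative
#' censoring of survivors. A raw vital-sign series is emitted whose
#' 30-minute window medians reproduce each record's worst-case values
#' exactly, so the preprocessing stage can be exercised end to end, and a
#' diagnosis table is emitted so the selection stage can be exercised
#' (decoy stays carry a late or primary PE entry).
#'
#' @param spec A [cohort_spec()].
#' @param emit_vitals Logical; emit the raw vitals series (default
#'   `TRUE`). Disable for large cohorts where only the records matter.
#' @return List with components `cohort` (records, schema of
#'   [cohort_schema()]), `vitals` (raw observations), `diagnoses`
#'   (diagnosis-list table for [select_secondary_pe()]) and `spec`.
#'   Reproducible: the same spec (including seed) yields an identical
#'   result.
#' @export
generate_cohort <- function(spec, emit_vitals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients + spec$n_decoys
  ids <- sprintf("pt%05d", seq_len(n))
  L <- rnorm(n)

  prev <- spec$prevalences
  lam <- spec$loadings
  crit <- list()
  for (nm in names(default_prevalences())) {
    z <- lam[[nm]] * L + sqrt(1 - lam[[nm]]^2) * rnorm(n)
    crit[[nm]] <- z > qnorm(1 - prev[[nm]])
  }

  age <- as.integer(round(pmin(pmax(rnorm(n, spec$age_mean, spec$age_sd),
                                    spec$age_min), spec$age_max)))

  rng <- vitals_value_ranges()
  flag_of <- c(heart_rate = "hr_high", resp_rate = "rr_high",
               sbp = "sbp_low", temperature = "temp_low",
               sao2 = "sao2_low")
  worst <- list()
  for (ch in names(rng)) {
    r <- rng[[ch]]
    fl <- crit[[flag_of[[ch]]]]
    lo <- ifelse(fl, r$flag[1], r$calm[1])
    hi <- ifelse(fl, r$flag[2], r$calm[2])
    worst[[ch]] <- round(runif_between(lo, hi), r$digits)
  }

  apache <- as.integer(round(exp(log(spec$apache_median) +
    spec$apache_slope * L + rnorm(n, 0, spec$apache_noise_sd))))

  dx_pool <- c("Sepsis, pulmonary", "Sepsis, renal/UTI (including bladder)",
               "Pneumonia, bacterial", "MI admitted > 24 hrs after onset",
               "CHF, congestive heart failure", "GI bleeding, lower",
               "CVA, cerebrovascular accident/stroke",
               "Rhythm disturbance (atrial, supraventricular)",
               "Respiratory arrest", "Emphysema/bronchitis")
  admission_dx <- sample(dx_pool, n, replace = TRUE)
  pe_dx_hours <- round(runif(n, 0.5, 48), 2)

  is_decoy <- seq_len(n) > spec$n_patients
  decoy_late <- is_decoy & (seq_len(n) %% 2 == 0)
  decoy_primary <- is_decoy & !decoy_late
  pe_dx_hours[decoy_late] <- round(runif(sum(decoy_late), 49, 120), 2)
  pe_dx_hours[decoy_primary] <- 0
  if (any(decoy_primary)) {
    admission_dx[decoy_primary] <- sample(default_dx_blocklist(),
                                          sum(decoy_primary), replace = TRUE)
  }

  records <- data.frame(
    patient_id = ids,
    age = age,
    male = crit$male,
    hx_heart_failure = crit$hx_heart_failure,
    hx_chronic_lung_disease = crit$hx_chronic_lung_disease,
    hx_chronic_cardiopulmonary = crit$hx_heart_failure |
      crit$hx_chronic_lung_disease | crit$cp_extra,
    hx_cancer = crit$hx_cancer,
    heart_rate_worst = worst$heart_rate,
    sbp_worst = worst$sbp,
    temp_worst = worst$temperature,
    resp_rate_worst = worst$resp_rate,
    sao2_worst = worst$sao2,
    altered_mental_status = crit$altered_mental_status,
    intubated = crit$intubated,
    vasoactive_infusion = crit$vasoactive_infusion,
    apache_iv = apache,
    died_in_hospital = FALSE,
    followup_days = 0,
    admission_dx = admission_dx,
    pe_dx_hours = pe_dx_hours,
    stringsAsFactors = FALSE)

  cls <- icu_spesi_class(icu_spesi_score(records))
  p_death <- class_anchored_death_prob(L, cls, spec$class_mortality,
                                       spec$severity_slope)
  died <- runif(n) < p_death
  death_time <- round(rlnorm(n, log(spec$death_time_median_days),
                             spec$death_time_sdlog), 2)
  records$died_in_hospital <- died
  records$followup_days <- ifelse(died, death_time, spec$censor_days)

  diagnoses <- rbind(
    data.frame(patient_id = ids, dx_text = admission_dx,
               minutes_from_admission = 0,
               is_primary_admission_dx = TRUE, stringsAsFactors = FALSE),
    data.frame(patient_id = ids, dx_text = "Embolism, pulmonary",
               minutes_from_admission = round(pe_dx_hours * 60),
               is_primary_admission_dx = decoy_primary,
               stringsAsFactors = FALSE))
  diagnoses <- diagnoses[order(diagnoses$patient_id,
                               diagnoses$minutes_from_admission), ,
                         drop = FALSE]
  rownames(diagnoses) <- NULL

  vitals <- NULL
  if (emit_vitals) {
    worst_window <- sample(1:5, n, replace = TRUE)
    parts <- vector("list", length(rng))
    for (i in seq_along(rng)) {
      ch <- names(rng)[i]
      r <- rng[[ch]]
      base <- round(runif_between(rep(r$base[1], 6 * n),
                                  rep(r$base[2], 6 * n)), r$digits)
      base_df <- data.frame(
        patient_id = rep(ids, each = 6),
        minutes_from_admission = rep(0:5 * 30 + 10, times = n),
        channel = ch,
        value = base,
        stringsAsFactors = FALSE)
      worst_df <- data.frame(
        patient_id = rep(ids, each = 3),
        minutes_from_admission = rep(worst_window, each = 3) * 30 +
          c(2, 12, 22),
        channel = ch,
        value = rep(worst[[ch]], each = 3),
        stringsAsFactors = FALSE)
      parts[[i]] <- rbind(base_df, worst_df)
    }
    vitals <- do.call(rbind, parts)
    vitals <- vitals[order(vitals$patient_id, vitals$channel,
                           vitals$minutes_from_admission), , drop = FALSE]
    rownames(vitals) <- NULL
  }

  list(cohort = records, vitals = vitals, diagnoses = diagnoses,
       spec = spec)
}

#' Published aggregate count fixture
#'
#' Per-stratum patient and death counts as printed in the source cohort's
#' results tables: the overall cohort (812 stays, 150 deaths), PESI
#' classes I-V, sPESI scores 0-5 and ICU-sPESI classes I-IV. Intended for
#' exact tests of proportion and confidence-interval operations; the
#' counts are published aggregates, not patient-level data.
#'
#' @return Data frame with columns `panel` (`"overall"`, `"pesi_class"`,
#'   `"spesi_score"`, `"icu_spesi_class"`), `level`, `n`, `deaths`.
#' @export
worked_fixture <- function() {
  data.frame(
    panel = c("overall",
              rep("pesi_class", 5),
              rep("spesi_score", 6),
              rep("icu_spesi_class", 4)),
    level = c("all",
              c("I", "II", "III", "IV", "V"),
              as.character(0:5),
              c("I", "II", "III", "IV")),
    n = c(812,
          58, 89, 90, 112, 463,
          111, 219, 242, 176, 56, 8,
          367, 303, 127, 15),
    deaths = c(150,
               2, 3, 4, 17, 124,
               10, 33, 42, 39, 22, 4,
               31, 58, 50, 11),
    stringsAsFactors = FALSE)
}
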