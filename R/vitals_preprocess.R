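#' Vital-sign channels
#'
#' The closed set of channels a vitals observation may carry.
#'
#' @return Character vector of channel names.
#' @export
vitals_channels <- function() {
  c("heart_rate", "sbp", "temperature", "resp_rate", "sao2")
}

# Direction in which each channel becomes score-triggering. Every cut-off
# used by PESI/sPESI/ICU-sPESI is one-sided: tachycardia and tachypnoea
# trigger high, hypotension, hypothermia and hypoxaemia trigger low.
worst_direction <- function() {
  c(heart_rate = "high", sbp = "low", temperature = "low",
    resp_rate = "high", sao2 = "low")
}

#' Median vital signs over tumbling 30-minute windows
#'
#' Reduces a raw vitals time series to one median per patient, channel and
#' non-empty 30-minute window. Windows are tumbling (non-overlapping) and
#' anchored at ICU admission, so window `k` covers minutes
#' `[30k, 30(k+1))`. Observations beyond the observation horizon are
#' ignored.
#'
#' @param obs Data frame with columns `patient_id`,
#'   `minutes_from_admission`, `channel`, `value`.
#' @param window_minutes Window width in minutes (default 30).
#' @param horizon_hours Only observations within this many hours of
#'   admission are used (default 48, the PE-diagnosis window).
#' @return Data frame with columns `patient_id`, `channel`,
#'   `window_index`, `median_value`, `n_obs`; empty windows produce no
#'   row. The median is the standard sample median (mean of the middle
#'   two for even counts).
#' @export
window_medians <- function(obs, window_minutes = 30, horizon_hours = 48) {
  stopifnot(window_minutes > 0, horizon_hours > 0)
  need <- c("patient_id", "minutes_from_admission", "channel", "value")
  missing_cols <- setdiff(need, names(obs))
  if (length(missing_cols)) {
    stop("vitals observations are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(obs$channel), vitals_channels())
  if (length(bad)) {
    stop("unknown vitals channel(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(obs$value))) {
    stop("non-finite vitals value", call. = FALSE)
  }
  if (any(obs$minutes_from_admission < 0)) {
    stop("negative observation time", call. = FALSE)
  }
  obs <- obs[obs$minutes_from_admission < horizon_hours * 60, , drop = FALSE]
  if (!nrow(obs)) {
    return(data.frame(patient_id = character(0), channel = character(0),
                      window_index = integer(0), median_value = numeric(0),
                      n_obs = integer(0), stringsAsFactors = FALSE))
  }
  obs$window_index <- as.integer(obs$minutes_from_admission %/% window_minutes)
  med <- aggregate(value ~ patient_id + channel + window_index, data = obs,
                   FUN = median)
  cnt <- aggregate(value ~ patient_id + channel + window_index, data = obs,
                   FUN = length)
  out <- merge(med, cnt,
               by = c("patient_id", "channel", "window_index"),
               suffixes = c("", ".n"))
  names(out)[names(out) == "value"] <- "median_value"
  names(out)[names(out) == "value.n"] <- "n_obs"
  out$n_obs <- as.integer(out$n_obs)
  out <- out[order(out$patient_id, out$channel, out$window_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Worst-case vitals per patient
#'
#' Collapses window medians to the most aberrant value per patient and
#' channel, in the direction of each score cut-off: maximum window median
#' for heart rate and respiratory rate, minimum for systolic blood
#' pressure, temperature and oxygen saturation. The result is invariant
#' to window order and idempotent. A channel with no window summary for a
#' patient yields `NA` (missingness is reported, not raised).
#'
#' @param summaries Output of [window_medians()].
#' @return Data frame with one row per patient and columns
#'   `heart_rate_worst`, `sbp_worst`, `temp_worst`, `resp_rate_worst`,
#'   `sao2_worst` (`NA` where a channel is missing).
#' @export
most_aberrant <- function(summaries) {
  dir <- worst_direction()
  worst_col <- c(heart_rate = "heart_rate_worst", sbp = "sbp_worst",
                 temperature = "temp_worst", resp_rate = "resp_rate_worst",
                 sao2 = "sao2_worst")
  ids <- sort(unique(summaries$patient_id))
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (ch in names(worst_col)) {
    sub <- summaries[summaries$channel == ch, , drop = FALSE]
    if (nrow(sub)) {
      f <- if (dir[[ch]] == "high") max else min
      vals <- tapply(sub$median_value, sub$patient_id, f)
      out[[worst_col[[ch]]]] <- as.numeric(vals[out$patient_id])
    } else {
      out[[worst_col[[ch]]]] <- NA_real_
    }
  }
  rownames(out) <- NULL
  out
}

#' Fill worst-case vitals onto cohort records
#'
#' Overwrites the five `*_worst` columns of `records` with values derived
#' from a raw vitals series via [window_medians()] and [most_aberrant()].
#' Patients without any observation on a channel keep `NA` there.
#'
#' @param records Cohort data frame.
#' @param worst Output of [most_aberrant()].
#' @return `records` with worst-case vitals replaced.
#' @export
apply_worst_vitals <- function(records, worst) {
  cols <- c("heart_rate_worst", "sbp_worst", "temp_worst",
            "resp_rate_worst", "sao2_worst")
  idx <- match(records$patient_id, worst$patient_id)
  for (col in cols) {
    records[[col]] <- worst[[col]][idx]
  }
  records
}
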