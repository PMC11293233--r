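#' Kaplan-Meier fit per group with administrative censoring
#'
#' Product-limit survival estimate per group. Follow-up is truncated at
#' `censor_at` days: a death occurring exactly at the boundary counts as
#' an event, any follow-up strictly beyond it is censored at the
#' boundary. Estimation is delegated to [survival::survfit()].
#'
#' @param times Follow-up in days (>= 0).
#' @param events Logical death indicators.
#' @param groups Group labels (default: a single group).
#' @param censor_at Administrative censoring time in days (default 55);
#'   `Inf` disables truncation.
#' @return Object of class `km_fit`: list with `curves` (data frame
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`), `groups`,
#'   `data` (the truncated analysis data) and `censor_at`. Survival is
#'   non-increasing within group and equals the empirical survival
#'   function when there is no censoring.
#' @export
km_fit <- function(times, events, groups = NULL, censor_at = 55) {
  if (any(is.na(times)) || any(times < 0)) {
    stop("follow-up times must be non-negative", call. = FALSE)
  }
  events <- as.logical(events)
  stopifnot(length(events) == length(times))
  if (is.null(groups)) groups <- rep("all", length(times))
  if (!length(groups)) stop("groups must be non-empty", call. = FALSE)
  g <- factor(groups)
  g <- droplevels(g)
  ev <- events & times <= censor_at
  tm <- pmin(times, censor_at)
  dat <- data.frame(time = tm, event = ev, group = g)
  fml <- survival::Surv(time, event) ~ group
  fit <- survival::survfit(fml, data = dat)
  if (nlevels(g) == 1) {
    strata_lab <- rep(levels(g), length(fit$time))
  } else {
    strata_lab <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata_lab,
                       time = fit$time,
                       n_risk = fit$n.risk,
                       n_event = fit$n.event,
                       n_censor = fit$n.censor,
                       surv = fit$surv,
                       stringsAsFactors = FALSE)
  rownames(curves) <- NULL
  structure(list(curves = curves, groups = levels(g), data = dat,
                 censor_at = censor_at),
            class = "km_fit")
}

#' Multi-group and pairwise log-rank tests
#'
#' k-group log-rank chi-square test (k - 1 degrees of freedom, ties
#' handled by the standard discrete hypergeometric variance) on a
#' [km_fit()], optionally followed by all unordered pairwise tests with
#' Bonferroni adjustment by the number of pairs tested within the family
#' (adjusted p = min(1, raw p x number of pairs)). Delegates to
#' [survival::survdiff()].
#'
#' @param fit A [km_fit()] with at least two groups.
#' @param pairwise Logical; also run all pairwise tests (default
#'   `FALSE`).
#' @return Object of class `logrank_result`: list with `statistic`,
#'   `df`, `p_value` and, when requested, `pairwise` (data frame
#'   `group1`, `group2`, `p_raw`, `p_adjusted`). A pair with no events
#'   in either group has an undefined statistic and is reported as `NA`.
#' @export
logrank <- function(fit, pairwise = FALSE) {
  stopifnot(inherits(fit, "km_fit"))
  dat <- fit$data
  k <- nlevels(dat$group)
  if (k < 2) stop("log-rank needs at least two groups", call. = FALSE)
  sd_all <- survival::survdiff(survival::Surv(time, event) ~ group,
                               data = dat)
  stat <- unname(sd_all$chisq)
  df <- k - 1
  res <- list(statistic = stat, df = df,
              p_value = pchisq(stat, df, lower.tail = FALSE))
  if (pairwise) {
    pairs <- combn(levels(dat$group), 2)
    n_pairs <- ncol(pairs)
    rows <- lapply(seq_len(n_pairs), function(i) {
      sub <- dat[dat$group %in% pairs[, i], , drop = FALSE]
      sub$group <- droplevels(sub$group)
      if (!any(sub$event)) {
        # no events in either group: the statistic is undefined
        p_raw <- NA_real_
      } else {
        sdp <- survival::survdiff(survival::Surv(time, event) ~ group,
                                  data = sub)
        chisq <- unname(sdp$chisq)
        p_raw <- if (is.finite(chisq)) {
          pchisq(chisq, 1, lower.tail = FALSE)
        } else {
          NA_real_
        }
      }
      data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                 p_raw = p_raw,
                 p_adjusted = min(1, p_raw * n_pairs),
                 stringsAsFactors = FALSE)
    })
    res$pairwise <- do.call(rbind, rows)
  }
  structure(res, class = "logrank_result")
}
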