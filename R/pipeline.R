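#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: the synthetic cohort
#' specification, selection window and diagnosis blocklist, vitals
#' windowing, confidence-interval method, censoring time and the seed.
#' One seed governs all randomness and is recorded in the output log.
#'
#' @param out_dir Directory for all outputs (created if needed).
#' @param seed Integer seed.
#' @param spec A [cohort_spec()]; defaults to `cohort_spec(seed = seed)`
#'   with `n_decoys = 40`, so the selection stage has work to do.
#' @param pe_window_hours Inclusion window for secondary PE (default 48).
#' @param dx_blocklist Admission-diagnosis blocklist (default
#'   [default_dx_blocklist()]).
#' @param window_minutes Vitals window width (default 30).
#' @param horizon_hours Vitals observation horizon (default 48).
#' @param ci_method `"wald"` or `"wilson"` (default `"wald"`).
#' @param censor_days Administrative censoring (default 55).
#' @param use_worked_fixture Logical; also report proportions and
#'   confidence intervals computed from the published aggregate count
#'   fixture ([worked_fixture()]) alongside the simulated cohort
#'   (default `TRUE`).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            spec = NULL,
                            pe_window_hours = 48,
                            dx_blocklist = default_dx_blocklist(),
                            window_minutes = 30,
                            horizon_hours = 48,
                            ci_method = c("wald", "wilson"),
                            censor_days = 55,
                            use_worked_fixture = TRUE) {
  ci_method <- match.arg(ci_method)
  if (is.null(spec)) {
    spec <- cohort_spec(seed = seed, n_decoys = 40,
                        censor_days = censor_days)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), spec = spec,
                 pe_window_hours = pe_window_hours,
                 dx_blocklist = dx_blocklist,
                 window_minutes = window_minutes,
                 horizon_hours = horizon_hours,
                 ci_method = ci_method,
                 censor_days = censor_days,
                 use_worked_fixture = use_worked_fixture),
            class = "pipeline_config")
}

score_columns <- function() {
  c(apache_iv = "apache_iv", pesi = "pesi", spesi = "spesi",
    icu_spesi = "icu_spesi")
}

mortality_by <- function(groups, died, ci_method) {
  lv <- levels(factor(groups))
  rows <- lapply(lv, function(g) {
    idx <- groups == g
    ci <- binomial_ci(sum(died[idx]), sum(idx), method = ci_method)
    data.frame(level = g, n = sum(idx), deaths = sum(died[idx]),
               mortality_pct = 100 * ci[["proportion"]],
               ci_lower_pct = 100 * ci[["lower"]],
               ci_upper_pct = 100 * ci[["upper"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full validation pipeline
#'
#' Executes simulate, select, preprocess, score, validate and survival
#' in order, writing every intermediate CSV, a machine-readable
#' `results.json` (full precision) and a run log recording seed and
#' versions. Rerunning with an identical configuration reproduces
#' identical outputs byte for byte.
#'
#' Stages: (1) generate the synthetic cohort, vitals series and
#' diagnosis table; (2) keep stays with a non-primary PE diagnosis
#' within the window and drop admission diagnoses suggestive of primary
#' PE; (3) reduce the vitals series to worst-case values and fill them
#' onto the records; (4) compute the four-score panel; (5) fit the
#' univariate logistic models, AUROCs, pairwise Hanley-McNeil
#' comparisons, calibration tables (deciles for APACHE-IV and PESI,
#' distinct values for sPESI and ICU-sPESI) and class-specific mortality
#' with confidence intervals; (6) Kaplan-Meier curves and log-rank tests
#' across PESI classes, sPESI scores and ICU-sPESI classes with
#' Bonferroni-corrected pairwise follow-up.
#'
#' When the realized cohort contains a single outcome class (for example
#' a zero-mortality configuration), the discrimination, calibration and
#' log-rank sections are omitted from the report; mortality proportions
#' and survival curves are still produced.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the results list (also written as JSON). Stage
#'   failures abort with the stage name.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- "simulate"
  res <- list(seed = config$seed)
  tryCatch({
    sim <- generate_cohort(config$spec)
    write_cohort(sim$cohort, out("cohort.csv"))
    write.csv(sim$vitals, out("vitals.csv"), row.names = FALSE)
    write.csv(sim$diagnoses, out("diagnoses.csv"), row.names = FALSE)

    stage <- "select"
    ids <- select_secondary_pe(sim$diagnoses,
                               window_hours = config$pe_window_hours)
    window_excluded <- data.frame(
      patient_id = setdiff(sim$cohort$patient_id, ids),
      reason = "no qualifying PE diagnosis within window",
      stringsAsFactors = FALSE)
    kept <- sim$cohort[sim$cohort$patient_id %in% ids, , drop = FALSE]
    sel <- exclude_primary_pe_dx(kept, blocklist = config$dx_blocklist)
    exclusions <- rbind(window_excluded, sel$excluded)
    write_exclusions(exclusions, out("exclusions.csv"))
    cohort <- sel$kept
    res$n_selected <- nrow(cohort)
    res$n_excluded <- nrow(exclusions)

    stage <- "preprocess"
    vit <- sim$vitals[sim$vitals$patient_id %in% cohort$patient_id, ,
                      drop = FALSE]
    worst <- most_aberrant(window_medians(vit,
                                          window_minutes = config$window_minutes,
                                          horizon_hours = config$horizon_hours))
    cohort <- apply_worst_vitals(cohort, worst)

    stage <- "score"
    panel <- score_panel(cohort)
    write.csv(panel, out("scores.csv"), row.names = FALSE)

    stage <- "validate"
    died <- cohort$died_in_hospital
    ci_all <- binomial_ci(sum(died), length(died), method = config$ci_method)
    res$overall <- list(n = length(died), deaths = sum(died),
                        mortality_pct = 100 * ci_all[["proportion"]],
                        ci_lower_pct = 100 * ci_all[["lower"]],
                        ci_upper_pct = 100 * ci_all[["upper"]])
    both_classes <- length(unique(died)) == 2
    if (both_classes) {
    aucs <- lapply(score_columns(), function(col) roc_auc(panel[[col]], died))
    res$auroc <- lapply(aucs, function(a) {
      list(auc = a$auc, se = a$se, n_pos = a$n_pos, n_neg = a$n_neg)
    })
    auc_df <- data.frame(score = names(aucs),
                         auc = vapply(aucs, `[[`, numeric(1), "auc"),
                         se = vapply(aucs, `[[`, numeric(1), "se"))
    write.csv(auc_df, out("auroc.csv"), row.names = FALSE)

    prs <- combn(names(score_columns()), 2)
    cmp_rows <- lapply(seq_len(ncol(prs)), function(i) {
      s1 <- prs[1, i]; s2 <- prs[2, i]
      cmp <- auroc_compare(panel[[s1]], panel[[s2]], died)
      data.frame(score1 = s1, score2 = s2, delta = cmp$delta, z = cmp$z,
                 p_value = cmp$p_value, r = cmp$r, stringsAsFactors = FALSE)
    })
    cmp_df <- do.call(rbind, cmp_rows)
    write.csv(cmp_df, out("auroc_comparisons.csv"), row.names = FALSE)
    res$auroc_comparisons <- cmp_df

    calib <- list()
    for (sc in names(score_columns())) {
      fit <- fit_logistic(panel[[sc]], died)
      mode <- if (sc %in% c("apache_iv", "pesi")) "deciles" else "distinct"
      tab <- calibration_table(fit, panel[[sc]], died, binning = mode)
      write.csv(tab, out(paste0("calibration_", sc, ".csv")),
                row.names = FALSE)
      calib[[sc]] <- list(intercept = fit$intercept, slope = fit$slope,
                          converged = fit$converged, binning = mode)
    }
    res$logistic <- calib
    }

    class_tabs <- list(
      pesi_class = mortality_by(panel$pesi_class, died, config$ci_method),
      spesi_score = mortality_by(panel$spesi, died, config$ci_method),
      icu_spesi_class = mortality_by(panel$icu_spesi_class, died,
                                     config$ci_method))
    for (nm in names(class_tabs)) {
      write.csv(class_tabs[[nm]], out(paste0("mortality_", nm, ".csv")),
                row.names = FALSE)
    }
    res$class_mortality <- class_tabs

    if (isTRUE(config$use_worked_fixture)) {
      wf <- worked_fixture()
      wf_ci <- t(mapply(function(k, n) binomial_ci(k, n,
                                                   method = config$ci_method),
                        wf$deaths, wf$n))
      wf$mortality_pct <- 100 * wf_ci[, "proportion"]
      wf$ci_lower_pct <- 100 * wf_ci[, "lower"]
      wf$ci_upper_pct <- 100 * wf_ci[, "upper"]
      write.csv(wf, out("published_counts_mortality.csv"),
                row.names = FALSE)
      res$published_counts <- wf
    }

    stage <- "survival"
    surv_groups <- list(pesi_class = panel$pesi_class,
                        spesi_score = panel$spesi,
                        icu_spesi_class = panel$icu_spesi_class)
    res$survival <- list()
    for (nm in names(surv_groups)) {
      fit <- km_fit(cohort$followup_days, died, surv_groups[[nm]],
                    censor_at = config$censor_days)
      write.csv(fit$curves, out(paste0("km_", nm, ".csv")),
                row.names = FALSE)
      if (both_classes) {
        lr <- logrank(fit, pairwise = TRUE)
        write.csv(lr$pairwise, out(paste0("logrank_pairwise_", nm, ".csv")),
                  row.names = FALSE)
        res$survival[[nm]] <- list(statistic = lr$statistic, df = lr$df,
                                   p_value = lr$p_value,
                                   pairwise = lr$pairwise)
      }
    }

    stage <- "report"
    jsonlite::write_json(res, out("results.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    log_lines <- c(
      sprintf("pesicu pipeline run"),
      sprintf("seed: %d", config$seed),
      sprintf("n_patients: %d, n_decoys: %d",
              config$spec$n_patients, config$spec$n_decoys),
      sprintf("package version: %s", as.character(packageVersion("pesicu"))),
      sprintf("R version: %s", R.version.string))
    writeLines(log_lines, out("run_log.txt"))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
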