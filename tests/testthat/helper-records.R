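# One-row cohort record with clinically unremarkable defaults; every
# score criterion is absent unless overridden.
make_record <- function(patient_id = "p1", age = 40, male = FALSE,
                        hx_heart_failure = FALSE,
                        hx_chronic_lung_disease = FALSE,
                        hx_chronic_cardiopulmonary = FALSE,
                        hx_cancer = FALSE,
                        heart_rate_worst = 80, sbp_worst = 120,
                        temp_worst = 37.0, resp_rate_worst = 16,
                        sao2_worst = 98,
                        altered_mental_status = FALSE, intubated = FALSE,
                        vasoactive_infusion = FALSE,
                        apache_iv = 50L, died_in_hospital = FALSE,
                        followup_days = 55, admission_dx = "Sepsis, pulmonary",
                        pe_dx_hours = 24) {
  data.frame(patient_id = patient_id, age = as.integer(age), male = male,
             hx_heart_failure = hx_heart_failure,
             hx_chronic_lung_disease = hx_chronic_lung_disease,
             hx_chronic_cardiopulmonary = hx_chronic_cardiopulmonary,
             hx_cancer = hx_cancer,
             heart_rate_worst = heart_rate_worst, sbp_worst = sbp_worst,
             temp_worst = temp_worst, resp_rate_worst = resp_rate_worst,
             sao2_worst = sao2_worst,
             altered_mental_status = altered_mental_status,
             intubated = intubated,
             vasoactive_infusion = vasoactive_infusion,
             apache_iv = as.integer(apache_iv),
             died_in_hospital = died_in_hospital,
             followup_days = followup_days, admission_dx = admission_dx,
             pe_dx_hours = pe_dx_hours, stringsAsFactors = FALSE)
}

# Cohort of n records with randomly flipped criteria (seeded by caller).
fuzz_cohort <- function(n) {
  flag <- function() runif(n) < 0.5
  data.frame(patient_id = sprintf("f%03d", seq_len(n)),
             age = as.integer(sample(18:99, n, replace = TRUE)),
             male = flag(),
             hx_heart_failure = flag(),
             hx_chronic_lung_disease = flag(),
             hx_chronic_cardiopulmonary = flag(),
             hx_cancer = flag(),
             heart_rate_worst = ifelse(flag(), 120, 80),
             sbp_worst = ifelse(flag(), 90, 120),
             temp_worst = ifelse(flag(), 35.5, 37),
             resp_rate_worst = ifelse(flag(), 32, 16),
             sao2_worst = ifelse(flag(), 85, 98),
             altered_mental_status = flag(),
             intubated = flag(),
             vasoactive_infusion = flag(),
             apache_iv = as.integer(sample(10:150, n, replace = TRUE)),
             died_in_hospital = flag(),
             followup_days = round(runif(n, 0.5, 55), 2),
             admission_dx = "Sepsis, pulmonary",
             pe_dx_hours = round(runif(n, 1, 47), 2),
             stringsAsFactors = FALSE)
}

# Independent tabulation of the PESI rubric: a data-driven point table
# evaluated row by row, deliberately not sharing code with pesi_score().
pesi_rubric_oracle <- function(p) {
  items <- list(
    list(pts = 10, f = function(r) r$male),
    list(pts = 10, f = function(r) r$hx_heart_failure),
    list(pts = 10, f = function(r) r$hx_chronic_lung_disease),
    list(pts = 20, f = function(r) r$heart_rate_worst >= 110),
    list(pts = 20, f = function(r) r$resp_rate_worst >= 30),
    list(pts = 20, f = function(r) r$temp_worst < 36),
    list(pts = 20, f = function(r) r$sao2_worst < 90),
    list(pts = 30, f = function(r) r$hx_cancer),
    list(pts = 30, f = function(r) r$sbp_worst < 100),
    list(pts = 60, f = function(r) r$altered_mental_status))
  vapply(seq_len(nrow(p)), function(i) {
    r <- p[i, , drop = FALSE]
    total <- floor(r$age)
    for (it in items) if (isTRUE(it$f(r))) total <- total + it$pts
    as.integer(total)
  }, integer(1))
}

# Textbook two-group log-rank oracle: at each distinct event time build
# the 2x2 risk table and accumulate observed-minus-expected events and
# the hypergeometric variance for group 1; statistic = (O - E)^2 / V.
logrank_oracle_2g <- function(time, event, group) {
  g1 <- group == unique(group)[1]
  oe <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & g1)
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oe^2 / v
}

# Exhaustive pairwise concordance AUROC (brute force over pos x neg).
auc_bruteforce <- function(scores, died) {
  pos <- scores[died]
  neg <- scores[!died]
  grid <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(grid)
}
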