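test_that("PESI worked examples follow the point rubric", {
  expect_equal(pesi_score(make_record(age = 40)), 40L)
  expect_equal(pesi_score(make_record(age = 75, male = TRUE,
                                      altered_mental_status = TRUE,
                                      sbp_worst = 90)), 175L)
  expect_equal(pesi_score(make_record(age = 60, hx_cancer = TRUE,
                                      heart_rate_worst = 112,
                                      temp_worst = 35.5,
                                      sao2_worst = 88)), 150L)
})

test_that("every printed threshold uses the printed comparator exactly", {
  expect_equal(pesi_score(make_record(heart_rate_worst = 110)), 60L)
  expect_equal(pesi_score(make_record(heart_rate_worst = 109.9)), 40L)
  expect_equal(pesi_score(make_record(resp_rate_worst = 30)), 60L)
  expect_equal(pesi_score(make_record(resp_rate_worst = 29.9)), 40L)
  expect_equal(pesi_score(make_record(temp_worst = 36.0)), 40L)
  expect_equal(pesi_score(make_record(temp_worst = 35.9)), 60L)
  expect_equal(pesi_score(make_record(sao2_worst = 90)), 40L)
  expect_equal(pesi_score(make_record(sao2_worst = 89.9)), 60L)
  expect_equal(pesi_score(make_record(sbp_worst = 100)), 40L)
  expect_equal(pesi_score(make_record(sbp_worst = 99)), 70L)
  # the sPESI age criterion is strictly greater than 80
  expect_equal(spesi_score(make_record(age = 80)), 0L)
  expect_equal(spesi_score(make_record(age = 81)), 1L)
})

test_that("risk-class maps reproduce their cutoffs at every boundary", {
  expect_equal(as.character(pesi_class(c(0, 65, 66, 85, 86, 105, 106, 125, 126))),
               c("I", "I", "II", "II", "III", "III", "IV", "IV", "V"))
  expect_error(pesi_class(-1), "non-negative")
  expect_equal(as.character(icu_spesi_class(c(0, 2, 3, 4, 5, 6, 7, 9))),
               c("I", "I", "II", "II", "III", "III", "IV", "IV"))
  expect_error(icu_spesi_class(10), "\\[0, 9\\]")
  expect_error(icu_spesi_class(-1), "\\[0, 9\\]")
})

test_that("sPESI and ICU-sPESI count their binary criteria exhaustively", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 9))
  names(grid) <- c("age_gt80", "cancer", "cp", "hr", "sbp", "sao2",
                   "intub", "ams", "vaso")
  co <- make_record()[rep(1, nrow(grid)), ]
  co$patient_id <- sprintf("g%03d", seq_len(nrow(grid)))
  co$age <- ifelse(grid$age_gt80, 85L, 40L)
  co$hx_cancer <- grid$cancer
  co$hx_chronic_cardiopulmonary <- grid$cp
  co$heart_rate_worst <- ifelse(grid$hr, 120, 80)
  co$sbp_worst <- ifelse(grid$sbp, 90, 120)
  co$sao2_worst <- ifelse(grid$sao2, 85, 98)
  co$intubated <- grid$intub
  co$altered_mental_status <- grid$ams
  co$vasoactive_infusion <- grid$vaso
  expect_equal(icu_spesi_score(co), as.integer(rowSums(grid)))
  expect_equal(spesi_score(co), as.integer(rowSums(grid[1:6])))
})

test_that("PESI matches an independent rubric tabulation over all 2^10 combinations", {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 10))
  names(grid) <- c("male", "hf", "cld", "hr", "rr", "temp", "sao2",
                   "cancer", "sbp", "ams")
  co <- make_record(age = 50)[rep(1, nrow(grid)), ]
  co$patient_id <- sprintf("g%04d", seq_len(nrow(grid)))
  co$male <- grid$male
  co$hx_heart_failure <- grid$hf
  co$hx_chronic_lung_disease <- grid$cld
  co$heart_rate_worst <- ifelse(grid$hr, 120, 80)
  co$resp_rate_worst <- ifelse(grid$rr, 35, 16)
  co$temp_worst <- ifelse(grid$temp, 35.0, 37.0)
  co$sao2_worst <- ifelse(grid$sao2, 85, 98)
  co$hx_cancer <- grid$cancer
  co$sbp_worst <- ifelse(grid$sbp, 90, 120)
  co$altered_mental_status <- grid$ams
  expect_equal(pesi_score(co), pesi_rubric_oracle(co))
})

test_that("flipping any single criterion never decreases any score", {
  set.seed(101)
  co <- fuzz_cohort(60)
  base <- data.frame(pesi = pesi_score(co), spesi = spesi_score(co),
                     icu = icu_spesi_score(co))
  flips <- list(
    function(x) { x$male <- TRUE; x },
    function(x) { x$hx_heart_failure <- TRUE; x },
    function(x) { x$hx_chronic_lung_disease <- TRUE; x },
    function(x) { x$hx_cancer <- TRUE; x },
    function(x) { x$hx_chronic_cardiopulmonary <- TRUE; x },
    function(x) { x$heart_rate_worst <- 120; x },
    function(x) { x$sbp_worst <- 90; x },
    function(x) { x$temp_worst <- 35.5; x },
    function(x) { x$resp_rate_worst <- 32; x },
    function(x) { x$sao2_worst <- 85; x },
    function(x) { x$altered_mental_status <- TRUE; x },
    function(x) { x$intubated <- TRUE; x },
    function(x) { x$vasoactive_infusion <- TRUE; x })
  for (f in flips) {
    mod <- f(co)
    expect_true(all(pesi_score(mod) >= base$pesi))
    expect_true(all(spesi_score(mod) >= base$spesi))
    expect_true(all(icu_spesi_score(mod) >= base$icu))
  }
})

test_that("score panels are internally consistent on fuzzed records", {
  set.seed(202)
  co <- fuzz_cohort(300)
  pan <- score_panel(co)
  expect_true(all(pan$spesi >= 0 & pan$spesi <= 6))
  expect_true(all(pan$icu_spesi >= 0 & pan$icu_spesi <= 9))
  expect_true(all(pan$icu_spesi >= pan$spesi))
  expect_true(all(pan$icu_spesi - pan$spesi <= 3))
  expect_true(all(pan$pesi >= co$age))
  expect_equal(pan$pesi_class, pesi_class(pan$pesi))
  expect_equal(pan$icu_spesi_class, icu_spesi_class(pan$icu_spesi))
  expect_equal(pan$apache_iv, co$apache_iv)
  # a zero-criterion 40-year-old: panel (40, I, 0, 0, I)
  zero <- score_panel(make_record(age = 40))
  expect_equal(zero$pesi, 40L)
  expect_equal(as.character(zero$pesi_class), "I")
  expect_equal(zero$spesi, 0L)
  expect_equal(zero$icu_spesi, 0L)
  expect_equal(as.character(zero$icu_spesi_class), "I")
})

test_that("a missing required vital raises an error naming the channel", {
  expect_error(pesi_score(make_record(sao2_worst = NA)), "sao2")
  expect_error(spesi_score(make_record(sbp_worst = NA)), "sbp")
})
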