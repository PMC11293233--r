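test_that("AUROC equals the exhaustive pairwise concordance oracle", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    died <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- sample(0:20, n, replace = TRUE)  # heavy ties
    got <- roc_auc(scores, died)
    expect_equal(got$auc, auc_bruteforce(scores, died))
    expect_equal(got$n_pos, sum(died))
    expect_equal(got$n_neg, sum(!died))
    expect_gte(got$se, 0)
  }
})

test_that("AUROC handles degenerate and transformed scores correctly", {
  died <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(roc_auc(c(rep(2, 10), rep(1, 10)), died)$auc, 1.0)
  expect_equal(roc_auc(rep(3, 20), died)$auc, 0.5)
  set.seed(13)
  s <- rnorm(60)
  d <- runif(60) < plogis(s)
  expect_equal(roc_auc(exp(s / 3), d)$auc, roc_auc(s, d)$auc)
  expect_error(roc_auc(s, rep(TRUE, 60)), "both outcome classes")
})

test_that("logistic slope equals the closed-form log odds ratio for a binary predictor", {
  # 2x2 table with odds ratio exactly 2: odds 20/80 vs 33/66
  scores <- c(rep(0, 100), rep(1, 99))
  died <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 33), rep(FALSE, 66))
  fit <- fit_logistic(scores, died)
  expect_true(fit$converged)
  expect_equal(fit$slope, log(2), tolerance = 1e-6)
  expect_equal(fit$intercept, log(20 / 80), tolerance = 1e-6)
})

test_that("the null slope is within 3 SE of zero under permuted labels", {
  set.seed(17)
  n <- 800
  scores <- rnorm(n)
  died <- sample(rep(c(TRUE, FALSE), c(200, 600)))
  fit <- fit_logistic(scores, died)
  se <- summary(glm(died ~ scores, family = binomial()))$coefficients[2, 2]
  expect_lt(abs(fit$slope), 3 * se)
})

test_that("degenerate logistic inputs are reported, not silently fitted", {
  expect_error(fit_logistic(rep(2, 10), rep(c(TRUE, FALSE), 5)), "constant")
  expect_error(fit_logistic(rnorm(10), rep(TRUE, 10)), "single class")
  sep <- fit_logistic(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5))
  expect_false(sep$converged)
})

test_that("calibration tables bin correctly and sum to the cohort", {
  # constant predicted probability: slope 0 fit
  flat <- structure(list(intercept = qlogis(0.3), slope = 0,
                         converged = TRUE, n = 50),
                    class = "logistic_fit")
  set.seed(19)
  scores <- rnorm(50)
  died <- runif(50) < 0.3
  tab <- calibration_table(flat, scores, died, binning = "deciles")
  expect_true(all(abs(tab$predicted - 0.3) < 1e-12))
  expect_equal(sum(tab$n), 50)

  spesi_like <- rep(0:5, times = c(10, 20, 25, 20, 15, 10))
  d2 <- runif(100) < plogis(-2 + 0.5 * spesi_like)
  if (length(unique(d2)) < 2) d2[1:2] <- c(TRUE, FALSE)
  fit2 <- fit_logistic(spesi_like, d2)
  tab2 <- calibration_table(fit2, spesi_like, d2, binning = "distinct")
  expect_equal(nrow(tab2), 6)
  expect_equal(tab2$n, c(10, 20, 25, 20, 15, 10))
})

test_that("a well-specified model calibrates within binomial error per decile", {
  set.seed(23)
  n <- 5000
  s <- rnorm(n, 50, 15)
  p <- plogis(-6 + 0.08 * s)
  died <- runif(n) < p
  fit <- fit_logistic(s, died)
  tab <- calibration_table(fit, s, died, binning = "deciles")
  for (i in seq_len(nrow(tab))) {
    se <- sqrt(tab$predicted[i] * (1 - tab$predicted[i]) / tab$n[i])
    expect_lt(abs(tab$observed[i] - tab$predicted[i]), 3 * se + 1e-9)
  }
})

test_that("Wald intervals reproduce published proportions from their counts", {
  overall <- binomial_ci(150, 812)
  expect_equal(round(100 * overall[["proportion"]], 1), 18.5)
  expect_equal(round(100 * overall[["lower"]], 1), 15.8)
  expect_equal(round(100 * overall[["upper"]], 1), 21.1)
  expect_equal(round(100 * binomial_ci(11, 15)[["proportion"]], 1), 73.3)
  zero <- binomial_ci(0, 10)
  expect_equal(zero[["proportion"]], 0)
  expect_equal(zero[["lower"]], 0)
  expect_error(binomial_ci(5, 4), "k <= n")
})

test_that("Wald interval width shrinks as 1/sqrt(n)", {
  w1 <- binomial_ci(30, 100)
  w4 <- binomial_ci(120, 400)
  expect_equal(w1[["upper"]] - w1[["lower"]],
               2 * (w4[["upper"]] - w4[["lower"]]))
})

test_that("group comparison picks the prescribed test per the decision rules", {
  # published cancer-by-survival counts: expected cells all >= 5
  grp <- rep(c("surv", "died"), c(662, 150))
  cancer <- c(rep(c(TRUE, FALSE), c(140, 522)),
              rep(c(TRUE, FALSE), c(45, 105)))
  res <- group_compare(cancer, grp, kind = "categorical")
  expect_equal(res$test, "chi-square")
  expect_equal(round(res$p_value, 3), 0.026)

  # identical groups: chi-square on identical proportions gives p = 1
  g2 <- rep(c("a", "b"), each = 100)
  v2 <- rep(rep(c(TRUE, FALSE), c(30, 70)), 2)
  same <- group_compare(v2, g2, kind = "categorical")
  expect_equal(same$p_value, 1)

  # an expected cell near 1 forces Fisher's exact test
  g3 <- rep(c("a", "b"), c(8, 8))
  v3 <- c(rep(TRUE, 2), rep(FALSE, 6), rep(TRUE, 1), rep(FALSE, 7))
  expect_equal(group_compare(v3, g3, kind = "categorical")$test, "fisher")

  set.seed(29)
  gn <- rep(c("a", "b"), each = 60)
  expect_equal(group_compare(c(rnorm(60), rnorm(60, 1)), gn,
                             kind = "continuous")$test, "t-test")
  expect_equal(group_compare(c(rexp(60), rexp(60, 0.5)), gn,
                             kind = "continuous")$test, "mann-whitney")
  expect_error(group_compare(1:5, rep("a", 5)), "two non-empty groups")
})

test_that("a score compared with itself gives delta 0, z 0, p 1", {
  set.seed(31)
  s <- rnorm(100)
  d <- runif(100) < plogis(s)
  cmp <- auroc_compare(s, s, d)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("swapping the scores negates z and preserves the p-value", {
  set.seed(37)
  s1 <- rnorm(200)
  s2 <- s1 + rnorm(200)
  d <- runif(200) < plogis(s1)
  ab <- auroc_compare(s1, s2, d)
  ba <- auroc_compare(s2, s1, d)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$r, ba$r)
})

test_that("with r = 0 the paired test reduces to the unpaired z-test", {
  set.seed(41)
  d <- runif(150) < 0.3
  a <- roc_auc(rnorm(150) + d, d)
  b <- roc_auc(rnorm(150) + 0.5 * d, d)
  cmp <- compare_auroc_paired(a, b, 0, 0)
  expect_equal(cmp$r, 0)
  expect_equal(cmp$z, (a$auc - b$auc) / sqrt(a$se^2 + b$se^2))
  expect_error(compare_auroc_paired(a, roc_auc(rnorm(100), runif(100) < 0.3),
                                    0, 0), "identical group sizes")
})

test_that("the AUC correlation term behaves like the published lookup function", {
  for (A in c(0.7, 0.8, 0.9)) {
    expect_equal(hm_auc_correlation(0, A, 100, 400), 0)
    expect_equal(hm_auc_correlation(1, A, 100, 400), 1)
    rs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(rho) hm_auc_correlation(rho, A, 100, 400),
                 numeric(1))
    expect_true(all(diff(rs) > 0))      # increasing in the score correlation
    expect_true(all(rs > 0 & rs < 1))
    expect_true(all(rs < c(0.1, 0.3, 0.5, 0.7, 0.9) + 0.05))
  }
})

test_that("Hanley-McNeil agrees with a DeLong oracle in accept/reject", {
  delong_p <- function(s1, s2, d) {
    r1 <- pROC::roc(d, s1, quiet = TRUE, direction = "<")
    r2 <- pROC::roc(d, s2, quiet = TRUE, direction = "<")
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE)$p.value
  }
  scenarios <- list(
    # clearly different discrimination: strong signal vs pure noise
    function(n) {
      x <- rnorm(n)
      d <- runif(n) < plogis(2 * x)
      list(s1 = x, s2 = rnorm(n), d = d)
    },
    # near-identical discrimination: same signal, tiny independent noise
    function(n) {
      x <- rnorm(n)
      d <- runif(n) < plogis(x)
      list(s1 = x + 0.1 * rnorm(n), s2 = x + 0.1 * rnorm(n), d = d)
    },
    # moderately correlated scores, one clearly stronger
    function(n) {
      x <- rnorm(n)
      d <- runif(n) < plogis(2 * x)
      list(s1 = x + 0.3 * rnorm(n), s2 = 0.3 * x + rnorm(n), d = d)
    })
  set.seed(43)
  for (make in scenarios) {
    for (rep in 1:3) {
      sc <- make(500)
      if (length(unique(sc$d)) < 2) next
      hm <- auroc_compare(sc$s1, sc$s2, sc$d)
      dl <- delong_p(sc$s1, sc$s2, sc$d)
      expect_equal(hm$p_value < 0.05, dl < 0.05)
    }
  }
})
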