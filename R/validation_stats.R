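#' Univariate logistic regression of mortality on a score
#'
#' Fits `P(death) = logistic(intercept + slope * score)` by maximum
#' likelihood (iteratively reweighted least squares, relative tolerance
#' 1e-8, at most 100 iterations). Complete or quasi-complete separation
#' is reported via `converged = FALSE` rather than silently diverging.
#'
#' @param scores Numeric vector.
#' @param died Logical vector of in-hospital death indicators.
#' @return List of class `logistic_fit` with `intercept`, `slope`,
#'   `converged`, `n`.
#' @export
fit_logistic <- function(scores, died) {
  stopifnot(length(scores) == length(died))
  died <- as.logical(died)
  if (length(unique(died)) < 2) {
    stop("outcome has a single class; cannot fit", call. = FALSE)
  }
  if (length(scores) < 2 || var(scores) == 0) {
    stop("score carries no information (constant)", call. = FALSE)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(died ~ scores, family = binomial(),
        control = glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  structure(list(intercept = unname(cf[1]),
                 slope = unname(cf[2]),
                 converged = isTRUE(fit$converged) && !separated &&
                   all(is.finite(cf)),
                 n = length(scores)),
            class = "logistic_fit")
}

#' Predicted death probability from a logistic fit
#'
#' @param fit A [fit_logistic()] result.
#' @param scores Numeric vector of score values.
#' @return Numeric vector of predicted probabilities.
#' @export
predict_logistic <- function(fit, scores) {
  stopifnot(inherits(fit, "logistic_fit"))
  plogis(fit$intercept + fit$slope * scores)
}

#' AUROC with the Hanley-McNeil standard error
#'
#' The area under the ROC curve computed as the tie-corrected rank
#' statistic: the proportion of (non-survivor, survivor) pairs in which
#' the non-survivor scores higher, ties counted half. The standard error
#' uses the Hanley-McNeil (1982) formula with
#' `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`.
#'
#' @param scores Numeric vector.
#' @param died Logical outcome vector; `TRUE` is the positive class.
#' @return List of class `auroc` with `auc`, `se`, `n_pos`, `n_neg`.
#' @references Hanley JA, McNeil BJ. Radiology 1982;143:29-36.
#' @export
roc_auc <- function(scores, died) {
  stopifnot(length(scores) == length(died))
  died <- as.logical(died)
  n_pos <- sum(died)
  n_neg <- sum(!died)
  if (n_pos == 0 || n_neg == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[died]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  structure(list(auc = auc, se = sqrt(max(v, 0)),
                 n_pos = n_pos, n_neg = n_neg),
            class = "auroc")
}

# P(Z1 > q, Z2 > q) for standard bivariate normal with correlation rho;
# q = qnorm(1 - A) so each margin has mass A. One-dimensional quadrature
# is exact enough here (abs.tol 1e-10).
bvn_upper_orthant <- function(rho, A) {
  q <- qnorm(1 - A)
  if (abs(rho) < 1e-12) return(A^2)
  if (rho >= 1 - 1e-12) return(A)
  if (rho <= -1 + 1e-12) return(max(0, 2 * A - 1))
  f <- function(u) dnorm(u) * pnorm((rho * u - q) / sqrt(1 - rho^2))
  integrate(f, lower = q, upper = Inf, abs.tol = 1e-10)$value
}

#' Correlation between two AUROC estimates from the same cases
#'
#' The correlation term `r` of the Hanley-McNeil (1983) method for
#' comparing correlated ROC areas, as a function of the average
#' within-group score correlation and the average area. It is computed
#' from the underlying bivariate-normal rating model the published
#' lookup table was derived from: paired score differences are bivariate
#' normal, and the covariance of the two rank-sum area estimates is
#' assembled from upper-orthant probabilities at correlation `rho`
#' (shared case pair), `rho / 2` (one shared case) and `1 / 2`
#' (within-modality shared case).
#'
#' @param rho Average of the within-survivor and within-non-survivor
#'   score correlations, in \[-1, 1\].
#' @param A Average of the two areas, in (0, 1).
#' @param n_pos,n_neg Group sizes.
#' @return Correlation in \[-1, 1\]; 0 when `rho = 0`, 1 when `rho = 1`.
#' @references Hanley JA, McNeil BJ. Radiology 1983;148:839-843.
#' @export
hm_auc_correlation <- function(rho, A, n_pos, n_neg) {
  stopifnot(rho >= -1, rho <= 1, A > 0, A < 1, n_pos >= 1, n_neg >= 1)
  if (abs(rho) < 1e-12) return(0)
  p_same <- bvn_upper_orthant(rho, A)
  p_shared <- bvn_upper_orthant(rho / 2, A)
  p_within <- bvn_upper_orthant(1 / 2, A)
  cov_u <- (p_same - A^2) + (n_pos + n_neg - 2) * (p_shared - A^2)
  var_u <- (A - A^2) + (n_pos + n_neg - 2) * (p_within - A^2)
  max(-1, min(1, cov_u / var_u))
}

#' Paired comparison of two correlated AUROCs (Hanley-McNeil)
#'
#' Compares two areas computed on the same cases:
#' `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)` with the
#' correlation term `r` from [hm_auc_correlation()] evaluated at the
#' average within-group score correlation and the average area; the
#' p-value is two-sided normal. With `r = 0` this reduces to the
#' unpaired two-sample z-test; swapping the two scores negates `z` and
#' leaves the p-value unchanged.
#'
#' @param a,b [roc_auc()] results for the two scores, computed on the
#'   same cases (equal group sizes enforced).
#' @param score_corr_pos Correlation of the two scores among
#'   non-survivors (Pearson by default upstream).
#' @param score_corr_neg Correlation of the two scores among survivors.
#' @return List of class `paired_auroc` with `delta` (`a$auc - b$auc`),
#'   `z`, `p_value`, `r`.
#' @export
compare_auroc_paired <- function(a, b, score_corr_pos, score_corr_neg) {
  stopifnot(inherits(a, "auroc"), inherits(b, "auroc"))
  if (a$n_pos != b$n_pos || a$n_neg != b$n_neg) {
    stop("paired comparison requires identical group sizes", call. = FALSE)
  }
  rho <- (score_corr_pos + score_corr_neg) / 2
  A_bar <- (a$auc + b$auc) / 2
  A_bar <- min(max(A_bar, 1e-8), 1 - 1e-8)
  r <- hm_auc_correlation(rho, A_bar, a$n_pos, a$n_neg)
  delta <- a$auc - b$auc
  denom <- sqrt(max(a$se^2 + b$se^2 - 2 * r * a$se * b$se, 0))
  z <- if (denom == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else {
    delta / denom
  }
  structure(list(delta = delta, z = z,
                 p_value = 2 * pnorm(-abs(z)), r = r),
            class = "paired_auroc")
}

#' Paired AUROC comparison from raw scores
#'
#' Convenience wrapper: computes both areas, the within-group Pearson
#' correlations, and the Hanley-McNeil paired comparison.
#'
#' @param scores1,scores2 Numeric score vectors on the same cases.
#' @param died Logical outcome vector.
#' @return A `paired_auroc` (see [compare_auroc_paired()]) with the two
#'   `auroc` objects attached as `auroc1`, `auroc2`.
#' @export
auroc_compare <- function(scores1, scores2, died) {
  died <- as.logical(died)
  a <- roc_auc(scores1, died)
  b <- roc_auc(scores2, died)
  safe_cor <- function(x, y) {
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  cmp <- compare_auroc_paired(a, b,
    score_corr_pos = safe_cor(scores1[died], scores2[died]),
    score_corr_neg = safe_cor(scores1[!died], scores2[!died]))
  cmp$auroc1 <- a
  cmp$auroc2 <- b
  cmp
}

#' Calibration table of observed vs predicted mortality
#'
#' Bins the cohort by score -- score deciles (quantile bins with merged
#' duplicate edges, so heavily tied scores may yield fewer than ten
#' bins) or distinct score values -- and tabulates per bin the number of
#' patients, the observed death proportion and the mean model-predicted
#' probability.
#'
#' @param fit A converged [fit_logistic()] result.
#' @param scores,died The data the fit was computed on.
#' @param binning `"deciles"` or `"distinct"`.
#' @return Data frame with columns `bin`, `n`, `observed`, `predicted`;
#'   the `n` column sums to the cohort size.
#' @export
calibration_table <- function(fit, scores, died,
                              binning = c("deciles", "distinct")) {
  binning <- match.arg(binning)
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  died <- as.logical(died)
  pred <- predict_logistic(fit, scores)
  bins <- if (binning == "deciles") {
    br <- unique(quantile(scores, probs = seq(0, 1, by = 0.1)))
    if (length(br) < 2) factor(rep(as.character(br[1]), length(scores)))
    else cut(scores, breaks = br, include.lowest = TRUE)
  } else {
    factor(scores)
  }
  out <- data.frame(
    bin = levels(bins),
    n = as.integer(table(bins)),
    observed = as.numeric(tapply(died, bins, mean)),
    predicted = as.numeric(tapply(pred, bins, mean)),
    stringsAsFactors = FALSE)
  out <- out[out$n > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binomial proportion with confidence interval
#'
#' Wald interval `p +/- z * sqrt(p (1 - p) / n)` truncated to \[0, 1\]
#' (default), or the Wilson score interval. The Wald default is the
#' convention under which published cohort proportions and their
#' intervals are reproduced exactly from the printed counts.
#'
#' @param k Number of events.
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @param method `"wald"` or `"wilson"`.
#' @return Named numeric vector `proportion`, `lower`, `upper`.
#' @export
binomial_ci <- function(k, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1", call. = FALSE)
  p <- k / n
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  c(proportion = p, lower = lo, upper = hi)
}

#' Two-group descriptive comparison
#'
#' Categorical variables: chi-square test, switching to Fisher's exact
#' test when any expected cell count is below 5. Continuous variables:
#' Shapiro-Wilk normality gate at alpha = 0.05 in each group, choosing
#' the two-sample t-test when both groups look normal and the
#' Mann-Whitney U test otherwise. (Shapiro-Wilk is evaluated on at most
#' 5000 values per group, its supported range.)
#'
#' @param values Numeric vector (continuous) or vector coercible to
#'   factor (categorical).
#' @param group Two-level grouping vector.
#' @param kind `"continuous"` or `"categorical"`.
#' @return List with `test` (name of the test chosen), `p_value`, and
#'   `statistic` where the test provides one.
#' @export
group_compare <- function(values, group, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("exactly two non-empty groups required", call. = FALSE)
  }
  if (kind == "categorical") {
    tab <- table(group, factor(values))
    expected <- suppressWarnings(chisq.test(tab)$expected)
    if (any(expected < 5)) {
      ft <- fisher.test(tab)
      list(test = "fisher", p_value = ft$p.value, statistic = NA_real_)
    } else {
      ct <- suppressWarnings(chisq.test(tab))
      list(test = "chi-square", p_value = ct$p.value,
           statistic = unname(ct$statistic))
    }
  } else {
    g <- split(as.numeric(values), group)
    normal <- vapply(g, function(x) {
      if (length(unique(x)) < 3) return(FALSE)
      shapiro.test(head(x, 5000))$p.value > 0.05
    }, logical(1))
    if (all(normal)) {
      tt <- t.test(g[[1]], g[[2]])
      list(test = "t-test", p_value = tt$p.value,
           statistic = unname(tt$statistic))
    } else {
      wt <- suppressWarnings(wilcox.test(g[[1]], g[[2]]))
      list(test = "mann-whitney", p_value = wt$p.value,
           statistic = unname(wt$statistic))
    }
  }
}
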