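---
title: "Validating PE mortality risk scores in the ICU: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating PE mortality risk scores in the ICU: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pesicu)
```

## The problem

Pulmonary embolism that develops *after* ICU admission for another
critical illness (secondary PE) carries a far higher mortality than PE as
an admission diagnosis, and it is not obvious that severity scores
designed for primary PE retain their prognostic value there. This package
provides the full desk-scale machinery for validating four candidate
mortality predictors in such a cohort — the general ICU score APACHE-IV
(consumed precomputed) and the PE-specific PESI, sPESI and ICU-sPESI —
together with a synthetic cohort generator that emulates the statistical
structure of a real secondary-PE ICU cohort, so that every analysis stage
is exercisable and testable without access-controlled patient data.

## Score calculators

The three PE-specific scores are deterministic functions of a patient
record:

* **PESI**: `floor(age)` points plus 10 each for male sex, heart-failure
  history, chronic-lung-disease history; 20 each for heart rate
  ≥ 110/min, respiratory rate ≥ 30/min, temperature < 36.0 °C, SaO~2~
  < 90%; 30 each for cancer history and systolic blood pressure
  < 100 mmHg; 60 for altered mental status. Risk classes use the original
  published strata (≤ 65 / 66–85 / 86–105 / 106–125 / > 125 → I–V); we
  adopt these as a documented assumption since only the class labels, not
  the cutoffs, appear in the validation context this package targets.
* **sPESI**: one point each (0–6) for age **strictly** greater than 80,
  cancer, chronic cardiopulmonary disease, heart rate ≥ 110, SBP < 100,
  SaO~2~ < 90.
* **ICU-sPESI**: sPESI plus one point each for intubation, altered mental
  status and vasoactive infusion (0–9), classed as ≤ 2 → I, 3–4 → II,
  5–6 → III, ≥ 7 → IV.

Every comparator is implemented exactly as printed and enforced by
boundary tests (110 triggers, 109.9 does not; 36.0 does not trigger, 35.9
does; 80 does not trigger the sPESI age item, 81 does; and so on).
"Chronic cardiopulmonary disease" is carried as its own boolean, distinct
from the separate heart-failure and chronic-lung-disease flags that feed
PESI, because the two parameterizations are genuinely different sets in
registry data; mapping raw comorbidity codes onto the combined flag is
the data producer's responsibility.

## Vital-sign preprocessing

Scores are computed from *worst-case* vitals: the raw time series is
reduced to medians over tumbling 30-minute windows anchored at ICU
admission, and the most aberrant window median per channel is kept —
maximum for heart rate and respiratory rate, minimum for SBP, temperature
and SaO~2~. Two choices here were genuinely open and are fixed as
configuration with documented defaults rather than claims about any
original extraction: windows are tumbling (not sliding), because fixed
30-minute bins are the deterministic reading of "medians over 30 min";
and the scan horizon defaults to the first 48 h of the stay, matching the
PE-diagnosis window. "Most aberrant" is one-sided per channel because
every cut-off in these scores is one-sided; a two-sided notion would be
underdetermined. A channel with no observations yields `NA` and is
reported as missing rather than raised, so missingness policy stays with
the caller (strict cohort reading treats missing worst-case vitals as key
data and excludes the stay).

## Cohort selection

A stay qualifies as secondary PE when a PE entry appears on the running
diagnosis list with a timestamp in `(0, 48]` hours and that entry is not
the primary admission diagnosis. A PE entry timestamped exactly at
admission is treated as present-on-admission (primary PE) and does not
qualify; this is a documented convention, chosen because an admission
timestamp cannot evidence a PE that *developed* in the ICU. Separately,
records whose free-text admission diagnosis matches a configurable
blocklist of phrases suggestive of primary PE (seven shipped defaults,
case-insensitive substring match) are excluded with a reason; the match
is substring-based because the phrases are illustrative rather than an
ontology.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once and are not tuning knobs.

* **Binary criteria.** A single standard-normal latent severity `L` per
  patient drives all criteria through a threshold model: criterion *i* is
  present when `λᵢ L + √(1−λᵢ²) εᵢ` exceeds the normal quantile of its
  target prevalence, so marginal prevalences are exact by construction
  while criteria are positively dependent. Independent criteria cannot
  produce the heavy upper tail of the observed risk-class distribution,
  which is why a latent factor is used at all. Acute markers (abnormal
  vitals, altered mental status, intubation, vasoactive support) load at
  0.60, chronic comorbidities at 0.20–0.25, sex at 0.05 (sex differs
  little by outcome in the motivating cohort). Target prevalences default
  to the published cohort composition (e.g. SBP < 100 in 54.2%,
  intubation 36.5%, cancer 22.8%).
* **Chronic cardiopulmonary disease** is the union of heart failure,
  chronic lung disease and a small independent top-up (p = 0.034, solved
  under independence to land the union near the published 42.7%). This
  keeps the flag logically consistent with its components at the price of
  an approximate rather than exact marginal prevalence.
* **Age** is truncated-normal (mean 66, SD 15, range 18–99; median 66,
  IQR ≈ 56–76) and independent of `L`, mirroring the observation that age
  above 80 did not separate survivors from non-survivors in the
  motivating cohort. The published IQR (53–76) is asymmetric; a symmetric
  model matching the median and upper quartile was preferred over a
  skewed age model the data do not constrain.
* **Worst-case vitals** are drawn uniformly from disjoint ranges strictly
  on the triggering or safe side of each cut-off, and the emitted raw
  series places each worst value in one randomly chosen 30-minute window
  (three identical observations, so the window median equals it exactly)
  on top of a strictly-less-aberrant baseline. Passing the series through
  the preprocessing stage therefore reproduces every record's worst-case
  values and threshold flags *exactly* — a designed invariant, tested.
* **Mortality.** Death is Bernoulli with probability anchored to the
  realized ICU-sPESI class (defaults 8.4 / 19.1 / 39.4 / 73.3% for
  classes I–IV) plus a residual within-class log-odds gradient in `L`
  (`severity_slope`, default 1.0 per SD). The per-class intercept is
  re-solved by root-finding on each draw so that the *mean* death
  probability within each realized class equals the class parameter
  exactly; the gradient therefore adds discrimination without moving
  class-level mortality. This residual term is what makes a
  latent-severity-linked APACHE-IV able to out-discriminate the
  PE-specific scores, as observed in real cohorts: were death a function
  of class alone, no score could beat the class variable in expectation.
* **APACHE-IV** is `round(exp(log(56) + 0.45·L + N(0, 0.2)))`: marginal
  median 56 and IQR ≈ 40–78, correlation ≈ 0.9 with latent severity.
* **Follow-up.** Death times are log-normal with median 6.2 days;
  `sdlog = 1.4` was fixed once as a compromise, since the published IQR
  (1.7–11.7 d) is more asymmetric than any log-normal can match on both
  sides (1.92 would match the lower quartile, 0.94 the upper). Survivors
  are censored administratively at 55 days.
* **Decoys.** Optionally the generator appends stays that the selection
  stage must reject — PE diagnosed after the window, or primary-PE
  admission diagnoses with a PE entry at admission — so the pipeline's
  filtering is exercised end to end.

What passing tests on this generator do **not** show: the generator makes
no attempt to reproduce the real cohort's joint distribution beyond the
stated margins, class-conditional mortality and a plausible dependence
structure, nor its admission-diagnosis casemix, nor measurement artifacts
in real vitals streams (no artifact filtering is implemented, because the
validated design declares none). Recovery of the published AUROC *values*
is therefore out of reach by design; only the qualitative ordering
(APACHE-IV above PESI and ICU-sPESI, sPESI last) is a generator contract,
and the test for it uses a dominant-severity configuration
(`severity_slope = 2`, `apache_noise_sd = 0.1`).

## Discrimination, calibration, group comparison

* **Logistic models** are univariate (`death ~ score`) maximum-likelihood
  fits via IRLS (relative tolerance 1e-8, 100 iterations max). Complete
  or quasi-complete separation is reported via `converged = FALSE`
  rather than returning silently diverged coefficients.
* **AUROC** is the tie-corrected rank statistic (ties half-credited, the
  convention under which the area equals the Mann–Whitney statistic),
  with the Hanley–McNeil standard error using `Q1 = A/(2−A)`,
  `Q2 = 2A²/(1+A)`.
* **Paired AUROC comparison** follows the Hanley–McNeil method for areas
  computed on the same cases:
  `z = (A₁−A₂)/√(SE₁² + SE₂² − 2 r SE₁ SE₂)`, with `r` a function of the
  average within-group score correlation (Pearson by default; the choice
  of coefficient is configurable input) and the average area. Rather than
  embedding a transcription of the published lookup table, `r` is
  computed at run time from the bivariate-normal rating model the table
  was derived from: paired score differences are bivariate normal, and
  the covariance of the two area estimates is assembled from three
  upper-orthant probabilities (shared case pair at correlation ρ, one
  shared case at ρ/2, within-modality shared case at 1/2) by
  one-dimensional Gaussian quadrature. This reproduces the tabulated
  function analytically — `r = 0` at ρ = 0, `r = 1` at ρ = 1, monotone
  between — avoids transcription risk, and removes the bilinear
  interpolation error. An independently implemented DeLong test (from
  pROC) is kept in the test suite as a cross-method oracle of
  accept/reject decisions; it is deliberately not the implementation.
* **Calibration tables** bin by score deciles (quantile cut with merged
  duplicate edges — heavily tied scores legitimately yield fewer than ten
  bins) for the wide-range scores, or by distinct score values for sPESI
  and ICU-sPESI, reporting per bin the size, observed death proportion
  and mean predicted probability.
* **Binomial intervals** default to Wald (`p ± z√(p(1−p)/n)`, truncated
  to [0, 1]) because that is the convention under which the published
  cohort proportions and intervals are reproduced exactly from their
  counts; Wilson is available as an option.
* **Two-group descriptives** follow the standard decision rules:
  chi-square (with Yates continuity correction for 2×2, which reproduces
  the published cancer-by-survival p-value of 0.026 exactly) switching to
  Fisher's exact test when any expected cell is below 5; for continuous
  variables a Shapiro–Wilk gate at α = 0.05 per group chooses between the
  t-test and the Mann–Whitney U test.

## Survival analysis

Kaplan–Meier curves are estimated per group after administrative
truncation at 55 days: a death exactly on the boundary counts as an
event, anything strictly beyond is censored at the boundary. The k-group
log-rank test uses the standard discrete hypergeometric variance
(correct under ties), with k−1 degrees of freedom; pairwise follow-up
tests are Bonferroni-adjusted by the number of pairs actually tested
within one family (one score's classes). A pair in which neither group
has any event has an undefined statistic and is reported `NA` rather
than 1 or 0. Estimation delegates to the survival package; the test
suite holds an independent per-event-time (O−E)²/V oracle against it,
and a 1000-replicate null simulation checks the rejection rate at
α = 0.05 to within three binomial standard errors.

## Numerical and degenerate-input choices

* Score thresholds are compared with the exact printed comparators; no
  tolerance is applied to clinical measurements.
* `roc_auc` on a constant score returns 0.5 (all ties); a single-class
  outcome is an error everywhere a discrimination quantity is undefined.
* In the paired comparison, a zero variance of the difference with a zero
  difference yields `z = 0, p = 1` (a score compared with itself).
* The generator's class-intercept root-finding brackets [−40, 40] on the
  log-odds scale and the orthant-probability quadrature uses an absolute
  tolerance of 1e-10; both are far inside double precision for every
  reachable input.
* Pipeline runs are deterministic byte-for-byte under a fixed seed; the
  run log records seed and versions but no timestamps.

## Problem sizes

The shipped tests and the acceptance script use cohorts of 120–5000
synthetic stays, 2^9–2^10 exhaustive criterion combinations, paired-score
simulations at n = 500, and 1000-replicate null calibrations — sizes
chosen so the whole suite completes in well under a minute on one core
while keeping every Monte-Carlo check inside three standard errors of its
target.

## Known limitations

* APACHE-IV is consumed precomputed; no attempt is made to model its 129
  input variables.
* The generator's dependence structure is a single-factor model with
  loadings that are design choices, not estimates of the real cohort
  (no criterion correlations are published to estimate them from).
* The PESI class cutoffs are the original published strata, adopted as an
  assumption.
* Calibration is assessed descriptively (observed vs predicted per bin);
  no Hosmer–Lemeshow or recalibration statistics are computed, matching
  the validated design.
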