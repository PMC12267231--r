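---
title: "Threshold dose-response analysis of admission lactate and 28-day mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold dose-response analysis of admission lactate and 28-day mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacthresh)
```

## The scientific question

First serum lactate at ICU admission marks tissue hypoperfusion and is a
standard prognostic biomarker in sepsis. In elderly sepsis cohorts the
association between lactate (mmol/L) and 28-day mortality is positive but
visibly non-linear: risk climbs steeply through the low-to-moderate range
and flattens at high concentrations. `lacthresh` implements the full
analysis pipeline around that question for a per-patient flat table —
descriptive baseline tables by exposure quartile, univariate and adjusted
logistic effect models, GAM dose-response smoothing, a two-piecewise
(threshold) logistic model with a grid-searched turning point, bootstrap
confidence interval and likelihood-ratio test, subgroup/interaction
analyses, and a calibrated synthetic cohort generator, since the motivating
ICU database is credentialed-access and cannot be redistributed.

## The threshold model

The core model is a logistic regression whose linear predictor is
continuous and piecewise-linear in the exposure $x$ with a single knot $K$:

$$
\operatorname{logit} P(Y = 1 \mid x, Z) =
\alpha + \beta_b \min(x, K) + \beta_a \max(x - K, 0) + \gamma^\top Z .
$$

The hinge terms $\min(x, K)$ and $\max(x-K, 0)$ always sum to $x$, so the
fitted logit is continuous at $K$ by construction (no jump term);
$e^{\beta_b}$ is the per-unit (per 1 mmol/L) odds ratio below the knot and
$e^{\beta_a}$ the per-unit odds ratio at or above it. Setting
$\beta_b = \beta_a$ recovers the ordinary one-line logistic model exactly —
the package asserts this identity numerically, and it is what makes the
one-line model nested in the piecewise model.

**Knot search.** $K$ is not estimated by smooth optimization; following the
threshold-regression practice this pipeline reproduces, the knot is
profiled over a predetermined grid: exposure values from the 5th to the
95th percentile in steps of 0.1 mmol/L (matching the one-decimal precision
at which turning points are conventionally reported). Each candidate is a
full ML fit; the candidate maximizing the log-likelihood wins, with ties
broken toward the smallest knot. Candidates whose fit fails — a segment
without both outcome classes, or an aliased design — are skipped and
recorded in the returned profile. `find_turning_point()` is tested to be
exactly equal to an independent brute-force refit loop over the same
candidates.

**Testing non-linearity.** The one-line and piecewise fits on the same data
are compared with a likelihood-ratio statistic $2\Delta\ell$ referred to
$\chi^2_1$ — one added slope-change parameter. This reference does not
account for the estimation of $K$ itself and is therefore mildly
anticonservative; it mirrors the common reporting practice in this
literature. Users who need a rigorous p-value can bootstrap the statistic
under the one-line null; the package keeps df = 1 as the default because
that is what published threshold tables of this kind report.

**Uncertainty in the knot.** The 95% CI for $K$ is a percentile bootstrap:
rows are resampled with replacement, the entire grid search is rerun per
replicate (the knot is re-estimated each time, not held fixed), and the
2.5/97.5 empirical percentiles of the replicate knots form the interval.
Replicates where every candidate is infeasible are dropped and counted;
more than 20% failures aborts with diagnostics. The seed is mandatory —
there is no silent default. BCa intervals are deliberately not offered: the
approach being reproduced reports percentile intervals.

## Effect models and descriptive conventions

* **Wald everywhere.** Odds ratios are $e^{\hat\beta}$ with CIs
  $e^{\hat\beta \pm 1.959964\,\mathrm{SE}}$ and two-sided Wald z p-values.
  The critical value is fixed at 1.959964 rather than 1.96 to avoid
  last-digit drift when results are rounded to two decimals for report
  tables. For a single binary regressor the logistic MLE on a saturated
  2×2 table is exact, so `fit_logistic()` and the closed-form
  `odds_ratio_2x2()` (Woolf interval) agree to machine-level tolerance —
  this dual route is used throughout the tests.
* **Adjustment sets.** `model_I` adjusts for age and gender; `model_II`
  for the full covariate list (demographics, comorbidities, first-24h
  vitals and labs, APACHE IV, SOFA, unit type). Unit type enters as
  reference-coded indicators with the largest group (medical-surgical ICU)
  as reference — the conventional choice where none is prescribed.
  Continuous covariates enter linearly and unscaled.
* **Quartile binning.** Cutpoints are the empirical 25/50/75 percentiles
  (linear interpolation of order statistics, the `stats::quantile` type-7
  default); intervals are left-closed/right-open except the last:
  $[\min,q_{25})$, $[q_{25},q_{50})$, $[q_{50},q_{75})$, $[q_{75},\max]$.
  Printed range labels in grouped reports round these cutpoints — the bins
  themselves are contiguous, as the near-equal group sizes of such tables
  imply.
* **Group tests.** The schema declares, per variable, whether the
  baseline table summarizes mean ± SD (one-way ANOVA), median (Q1–Q3)
  (Kruskal–Wallis H), or n (%) (Pearson chi-squared without continuity
  correction; a flag enables the Yates correction for small 2×2 tables).
  Declaring normal-vs-skewed in the schema rather than auto-testing keeps
  runs reproducible; the default schema marks WBC, BUN, SOFA and ICU
  length of stay as skewed (median/IQR) and the remaining continuous
  variables as mean ± SD.
* **P-value display.** Baseline tables floor at "< 0.001" (3 decimals);
  effect tables at "< 0.0001" (4 decimals).
* **Exclusions.** Age < 65 years, ICU stay < 24 h, no sepsis diagnosis,
  no lactate measurement — applied sequentially in that order with each
  removed row attributed to the first criterion it fails, so the
  flow-chart counts plus the retained n always reconstruct the input n.
  Whether the original cohort selection was sequential or union-style is
  not recoverable from the published total alone; sequential attribution
  is the flow-chart convention and is idempotent.
* **Missing data.** Median imputation for continuous covariates (even
  counts use the mean of the two central order statistics), mode for
  binary/categorical; exposure and outcome are never imputed. A
  complete-case sensitivity variant reruns the whole pipeline without
  imputation.

## The dose-response smooth

`fit_smooth()` fits a binomial GAM with a fixed-dimension thin-plate
regression spline in lactate (default 4 degrees of freedom — the
conventional dose-response default, flexible enough for a single bend
without chasing noise) plus linear covariate terms, and evaluates the
centered partial effect of lactate on the log-odds scale over 200 grid
points spanning the observed range, with a pointwise 95% Wald band.
`spline_df = 1` is by definition a straight line, so it is fit as a plain
linear logistic model and reproduces `fit_logistic()` exactly — a useful
degenerate case for testing. For SOFA-stratified curves
(`stratified_smooth()`, default cut ≤ 5 vs > 5, configurable) the curves
are reported on the full adjusted log-odds scale (intercept included,
covariates held at stratum means) rather than centered: stratified curves
answer "how does absolute risk differ", and centering would erase exactly
the baseline-risk separation of interest. Strata are fit independently and
re-evaluated on a common exposure grid for pointwise comparison.
Interpretation should focus on the central exposure range; beyond roughly
the 95th percentile the spline extrapolates from sparse data and its
wiggles are not evidence.

## Subgroups and interaction

For each prespecified stratifier (HR, temperature, potassium, WBC,
bicarbonate, RDW, BUN, APACHE IV, SOFA), continuous variables are split at
the in-sample median (low = at or below; the cut value is echoed in the
output since no external cutoffs are prescribed), the adjusted per-unit
lactate OR is estimated within each stratum with the stratifier removed
from its own covariate set, and one interaction p-value per stratifier
comes from a likelihood-ratio test of the pooled model with vs without a
lactate × stratum product term (df = number of strata − 1). Strata too
degenerate to fit are flagged and skipped without aborting the run. No
multiplicity correction is applied across subgroups, matching the
forest-plot convention being reproduced. Under the no-modification null
the test's empirical size at nominal 0.05 is verified by simulation in the
test suite (500 replicates of n = 2,000).

## The synthetic cohort generator

The motivating database is credentialed-access, so the pipeline is
exercised end-to-end on a synthetic twin. The generator's defaults are the
published cohort conditions and are deliberately not tuning knobs:

* n = 5,150; marginal 28-day mortality 13.8%;
* lactate from a shifted log-normal whose three parameters are solved in
  closed form so its quartiles equal 1.50 / 2.10 / 3.27 mmol/L exactly
  (the shift has the closed form
  $s = (q_{25}q_{75} - q_{50}^2)/(q_{25} + q_{75} - 2q_{50})$, valid for
  right-skewed targets), capped at 30 mmol/L;
* outcome from the piecewise-logit mechanism with K = 3.7 mmol/L and
  per-unit segment ORs 1.33 / 1.11; the intercept is calibrated by root
  finding so the realized-draw marginal event rate hits the target within
  2×10⁻³;
* covariates drawn independently from marginals matched to the published
  baseline table (truncated normals for vitals and labs, shifted
  log-normals for the skewed WBC and BUN, a rounded truncated normal for
  SOFA, multinomial unit type), with modest log-OR effects on the outcome
  for the clinically active ones (e.g. SOFA 0.13 per point, APACHE IV
  0.015 per point, bicarbonate −0.05 per mmol/L) — values chosen once as
  realistic magnitudes for this population;
* per-variable MCAR missingness matched to the published missingness
  footnote (e.g. RDW 9.36%, APACHE IV 11.79%), applied after the outcome
  draw, matching the median-imputation remedy downstream;
* administrative columns (ICU stay, sepsis flag, measurement count, death
  time) filled so the default cohort passes the exclusion filter
  unchanged.

What the generator does **not** emulate: cross-correlations among
covariates and between covariates and lactate (no empirical copula — e.g.
the real cohort's falling bicarbonate with rising lactate), informative
(MAR/MNAR) missingness, and any within-stay time structure. Passing tests
on this generator therefore demonstrate estimator correctness under the
stated marginal conditions, not robustness to the dependence structure of
real ICU data. An optional `stratum_modifiers` hook adds stratum-specific
intercept or slope shifts for effect-modification experiments, and every
generated cohort embeds its truth for `truth_report()` scoreboards.

## Numerical choices

* Logistic fits use IRLS (`stats::glm`/`glm.fit`) with deviance tolerance
  10⁻¹⁰ and up to 100 iterations; complete/quasi-complete separation and
  rank deficiency raise explicit errors instead of returning inflated
  estimates; outcomes with a single class are rejected up front.
* The grid scan warm-starts each candidate's IRLS at the previous
  candidate's solution (adjacent knots have near-identical MLEs), and
  bootstrap replicates start from the full-data solution; this changes
  runtime, not results, since every fit still converges to the same
  tolerance.
* Missing markers accepted on input: empty cell, "NA", "NaN"
  (case-insensitive). Unparseable numeric cells become missing; outcome
  values outside {0, 1} and non-positive exposures are validation errors.
* Degenerate inputs have named errors throughout: constant exposure
  (binning), zero 2×2 cells (closed-form OR), empty strata
  (stratification), all-missing columns (imputation), empty candidate
  grids (search), > 20% failed bootstrap replicates.

## Known limitations

* **The knot is weakly identified at the reference effect sizes.** With
  n ≈ 5,000, ~14% events and a logit slope change of only
  $\ln 1.33 - \ln 1.11 \approx 0.18$, the profile likelihood over $K$ is
  shallow. The test suite's recovery experiment (100 cohorts at the
  generating truth, clean marginals) finds the grid estimate
  median-unbiased (median $\hat K$ = 3.7) but with a median absolute
  error of about 0.9 mmol/L, and single realizations can place $\hat K$
  far from the truth. Wide percentile-bootstrap intervals for $K$ are the
  honest reflection of this. Segment slopes evaluated **at the estimated
  knot** inherit post-selection bias (the below-segment slope is
  overestimated on average and its nominal 95% CI undercovers); evaluated
  at the generating knot the slopes are unbiased with near-nominal
  coverage, which is how the recovery tests separate the two effects.
* The LRT df = 1 reference ignores knot estimation (anticonservative).
* Reported per-unit ORs are conditional (covariate-adjusted) effects;
  because the generator draws covariates independently, its crude and
  adjusted ORs nearly coincide — real cohorts show confounding the
  generator does not.
* The pipeline models a fixed-window binary outcome; no time-to-event
  structure.

## Problem sizes used by the tests

The suite exercises the estimators at the reference cohort size (n =
5,150) where the property under test concerns the study conditions (the
100-replicate recovery run, LRT power, generator calibration), and at
n = 800–20,000 elsewhere, chosen per test as the smallest size at which
the property is stable: oracle-equivalence scans at n = 800–900, smooth
shape and band properties at n = 3,000–20,000, interaction power at
n = 20,000, null calibration at 500 × n = 2,000, and the bootstrap
determinism/coverage spot-check at n = 6,000 with B = 60. The analysis
drivers under `analysis/` run the full pipeline at n = 5,150 with B = 200
bootstrap replicates.
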