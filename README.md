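# lacthresh

Threshold ("two-piecewise") dose-response analysis of admission serum
lactate and 28-day mortality in elderly ICU sepsis cohorts.

Admission lactate is a standard hypoperfusion marker, but its association
with short-term mortality in elderly sepsis patients is non-linear: risk
rises steeply through the low-to-moderate range and flattens above a
turning point. This package implements the complete analysis a clinical
epidemiologist would run on a per-patient flat table to characterize that
threshold, for cohorts whose source databases (credentialed ICU EHR
archives) cannot be redistributed — so it also ships a calibrated
synthetic cohort generator that emulates the published marginals of a
reference elderly-sepsis cohort (n = 5,150, lactate quartiles
1.50/2.10/3.27 mmol/L, 13.8% 28-day mortality).

## The model

The core is a logistic regression whose linear predictor is continuous and
piecewise-linear in lactate `x` with a single knot `K` (hinge
parameterization):

    logit P(death | x, Z) = a + b_below * min(x, K) + b_above * max(x - K, 0) + c'Z

`exp(b_below)` and `exp(b_above)` are the per-1-mmol/L odds ratios below
and at/above the turning point. `K` is profiled over a grid (5th-95th
exposure percentile, 0.1 mmol/L steps) by maximum likelihood; the one-line
model (nested: `b_below = b_above`) is compared by likelihood-ratio test,
and a percentile bootstrap (grid search rerun on each row-resample) gives
the 95% CI for `K`. Around this sit the standard pipeline stages:
exclusion filtering, median imputation, quartile binning, baseline
(Table-1 style) summaries with ANOVA / Kruskal-Wallis / chi-squared group
tests, crude and adjusted logistic effect tables with Wald intervals, GAM
dose-response curves (pooled and SOFA-stratified), and subgroup effects
with interaction LRTs. See `vignettes/threshold-analysis.Rmd` for the
methods account.

## Worked example

Quantities recomputable from published 2x4 quartile counts alone
(deaths/survivors per lactate quartile 97/1177, 111/1127, 174/1176,
329/959):

```r
library(lacthresh)
odds_ratio_2x2(329, 959, 97, 1177)   # Q4 vs Q1
#>      term odds_ratio   ci_low  ci_high      p_value
#> 1 exposed   4.162766 3.268111 5.302335 7.194268e-31
proportion_ci(711, 5150)             # pooled 28-day mortality
#> $proportion 0.1380583   $ci_low 0.1286369   $ci_high 0.1474796
```

The full pipeline on the synthetic cohort (drivers under `analysis/`,
numbered in execution order) prints, for seed 20250929:

```
$ Rscript analysis/01_simulate.R
generated 5150 stays; exclusions removed 0 (...)
realized event rate 0.135 (target 0.138); lactate quartiles 1.49/2.1/3.22

$ Rscript analysis/02_descriptives.R
28-day mortality 13.5% (696/5150), 95% CI 12.58-14.45%

$ Rscript analysis/04_threshold.R
turning point K = 3.1 mmol/L, bootstrap 95% CI (2.1, 5.4), 0/200 replicates failed
per-unit OR below K: 1.58 (1.39, 1.79)
per-unit OR at/above K: 1.13 (1.10, 1.17)
one-line vs piecewise LRT: statistic 20.667, p < 0.0001
```

Reading: this realization of the generator (true knot 3.7, segment ORs
1.33/1.11) yields a knot estimate of 3.1 with a wide bootstrap interval —
at these effect sizes the knot is weakly identified at n ≈ 5,000, which
the interval reports honestly; the steep-then-flat segment structure and
the LRT's rejection of the one-line model are stable across realizations.
`analysis/05_smooth_curves.R` and `analysis/06_subgroups.R` produce the
curve and forest-table outputs, `analysis/07_sensitivity.R` the
complete-case and early-death sensitivity variants.

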