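---
title: "Methods: validating MUAC as an adolescent overweight screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating MUAC as an adolescent overweight screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muacscreen)
```

# The scientific question

Mid-upper arm circumference (MUAC) is a one-tape measurement long used to
screen for acute undernutrition. This package implements the statistical
machinery for the converse question: how accurately does MUAC identify
*overweight* (including obesity) in adolescents, when the reference
classification is a BMI-for-age Z-score above +1 SD? The analysis treats
MUAC as a continuous index test and BMI-Z-defined overweight as the binary
reference, and evaluates discrimination (ROC/AUC), cutoff choice (Youden
index), the resulting diagnostic-metric panel, internal validity (bootstrap
optimism) and calibration.

# The measurement model

Field anthropometry takes every measurement twice; the analysis value is the
pair average. For MUAC, a pair disagreeing by more than 0.5 cm triggers a
repeat pair whose average replaces the original
(`average_replicates()`). Measurer quality is summarized by the technical
error of measurement, TEM = sqrt(sum(d_i^2) / 2n) over replicate pairs.

BMI-for-age Z-scores use the LMS parameterization of a growth reference:
a Box-Cox power `L`, median `M` and coefficient of variation `S` per sex and
age-month, with

$$ z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
   z = \frac{\log(x/M)}{S} \quad (L = 0). $$

Beyond ±3 SD the raw Box-Cox score is rescaled linearly between the ±2 and
±3 SD curves (`z = 3 + (x - sd_3)/(sd_3 - sd_2)` above +3, mirrored below
−3), the restricted-tail convention of the WHO growth software; this keeps
extreme BMIs finite and makes `lms_zscore()` and `lms_inverse()` exact
inverses over the whole real line. Subjects are matched to the reference by
sex and nearest age in months — reference tables are monthly, and
nearest-month matching is what common implementations do; linear
interpolation in age is available behind a flag. Status uses the WHO
school-age convention with *strict* inequalities: overweight including
obesity is z > +1, obesity z > +2 (the +2 threshold is the usual WHO
convention; only the +1 rule is stated explicitly in the screening
literature this package addresses).

When the input table carries a precomputed `bmi_z` column, the LMS
machinery is bypassed entirely, so the pipeline runs without any reference
table. The package deliberately does not ship WHO reference values; the
built-in `synthetic_lms()` table is plausible but synthetic, and is used
only to back-solve weights in the cohort generator.

# Diagnostic metrics and their intervals

A subject is screen-positive when `marker >= cutoff` (cutoffs are
conventionally printed as "≥ 27.75"). From the 2×2 table: sensitivity
TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP), NPV TN/(TN+FN),
accuracy (TP+TN)/n, Youden J = Se + Sp − 1, LR+ = Se/(1−Sp),
LR− = (1−Se)/Sp. Metrics with zero denominators are reported as explicitly
undefined rather than dropped or zeroed.

Interval choices:

- **Proportions**: exact Clopper–Pearson from beta quantiles. The choice is
  deliberate: on the canonical 112/123 sensitivity the exact interval
  reproduces the conventionally reported (84.6–95.5) at one decimal, which
  the Wilson interval does not.
- **Likelihood ratios**: the Simel log-method,
  `exp(log LR ± z·SE)` with `SE² = 1/TP − 1/(TP+FN) + 1/FP − 1/(FP+TN)`
  for LR+ (analogously for LR−); zero cells yield an explicit
  undefined-interval result.
- **AUC**: DeLong structural-components variance (the de-facto standard
  when no method is stated), truncated to [0, 1]; a seeded
  bootstrap-percentile alternative is available for sensitivity analysis.
  Perfect separation gives zero DeLong variance and a degenerate interval
  with a warning.
- **Spearman rho**: Fisher-z with the rank-correlation variance inflation,
  SE = sqrt(1.06/(n−3)).

The empirical AUC is the Mann–Whitney two-sample rank statistic (ties
counted ½), computed from midranks; it is identical to the trapezoidal area
under the empirical ROC, and the tests assert this to 1e−12.

The Youden-optimal cutoff maximizes J over the *observed* marker values
(not midpoints): with readings recorded to 0.1 cm and averaged in pairs,
published optima such as 27.75 are attainable observed averages, while
midpoints would manufacture unattainable thresholds. Ties in J break toward
the smallest cutoff, i.e. toward sensitivity, which is the right direction
for a screening instrument.

# Internal validation

The probability model behind validation is a univariable logistic
regression of reference status on MUAC — the only model consistent with
"predicted probability (using MUAC)". Optimism correction follows the
standard bootstrap: refit on each resample, compare the resample
(apparent) AUC with the AUC of that model transported to the original data,
and subtract the mean difference from the original AUC. Degenerate
one-class resamples are redrawn, not skipped, so exactly `n_boot` resamples
contribute; everything is reproducible from the seed.

A structural point the tests assert explicitly: because AUC is invariant
under monotone transforms, a positive-slope univariable model has
`test AUC = original marker AUC` exactly, so the optimism reduces to
`mean(AUC_boot − AUC_original)`. Its expectation is essentially zero — a
single-predictor model has no effective capacity to overfit — so the
corrected AUC should and does sit within a few 1e−4 of the apparent AUC.
Study-scale analyses that report optimism near 0.007 are consistent with
this: the correction is negligible at n ≈ 851.

Calibration uses the Hosmer–Lemeshow grouped chi-square with 10
equal-count bins of predicted probability (df = bins − 2; zero-expected
bins are collapsed into a neighbour with a df adjustment and warning),
plus the calibration slope and intercept from refitting the outcome on the
linear predictor. On training data the logistic score equations force
slope 1 and intercept 0, which the tests verify to 1e−6; the H-L test's
null size (~5% at α = 0.05) is verified by simulation over 400 seeded
replicates. H-L is the default grouped calibration test when none is
named; the bin count is configurable.

# The synthetic cohort generator

`generate_cohort()` emulates a two-sex school cohort with the marginals the
package is tested against: 456 males and 395 females; MUAC 25.3 ± 3.2 cm
(male) and 25.7 ± 3.4 cm (female); BMI Z −0.8 ± 1.2 and −0.05 ± 1.1; age
16.7 ± 1.1 years; height 168.7 ± 6.8 and 157.0 ± 6.3 cm; pooled
Spearman(MUAC, BMI Z) target 0.81. Mechanics:

- **Gaussian copula with normal marginals.** Only means and SDs are
  available as study conditions, so normality is the minimal assumption.
  Within each sex, (MUAC, BMI Z) is bivariate normal.
- **Pooled-rank calibration.** For a bivariate normal the Spearman and
  Pearson correlations are linked by `r = 2 sin(π r_s / 6)`
  (`spearman_to_pearson()`). Pooling two strata with different marginals
  *attenuates* the rank correlation, and the published correlation is a
  pooled quantity; the generator therefore calibrates the shared latent
  Pearson correlation numerically (Gauss–Hermite quadrature of
  `12 E[F(X)G(Y)] − 3` over the mixture, `pooled_spearman()`) so the pooled
  population Spearman hits the target. With identical strata this reduces
  exactly to the closed-form map, which the tests assert.
- **Emergent prevalence.** Overweight status follows from the BMI-Z
  marginals; nothing forces a prevalence. Under these Gaussian marginals
  the implied P(Z > 1) is ≈ 0.115 and P(Z > 2) ≈ 0.02. Real adolescent
  BMI-Z distributions are right-skewed, so real cohorts can show somewhat
  higher overweight/obesity fractions (e.g. 14.5% combined) at the same
  means and SDs — a deliberate limitation of the normal-marginal
  assumption rather than a calibration error. A `forced_prevalence` mode
  shifts both strata to any target tail mass for power experiments.
- **Measurement layer.** Weight is back-solved from BMI Z via the LMS
  inverse at the subject's age and drawn height. Every measurement is
  emitted as two replicates = truth + independent N(0, 0.1²) noise, rounded
  to the 0.1 cm/kg instrument precision (rounding after noise, mirroring
  the protocol); MUAC pairs disagreeing by > 0.5 cm receive a repeat pair.
  The default replicate noise SD of 0.1 is the instrument's recording
  resolution — a well-standardized measurer reproduces a tape reading to
  about one graduation.
- **What it does not emulate**: school-level clustering and the multistage
  sampling design (the analysis is unweighted by scope), age-dependence of
  MUAC (observed weak, r ≈ 0.15, and not part of the copula), and the
  BMI-Z right skew noted above. Passing tests on synthetic cohorts
  therefore demonstrate correctness of the estimators and the pipeline
  machinery, not distributional fidelity to any particular field dataset.

# Numerical and design choices

- AUC accuracy bands: excellent [0.9, 1], good [0.8, 0.9), fair [0.7, 0.8),
  poor [0.6, 0.7), fail [0.5, 0.6); shared endpoints belong to the upper
  band; AUC < 0.5 is "fail" with a warning.
- Logistic fits run IRLS to a 1e−10 relative tolerance (100 iterations
  max); perfect and quasi-perfect separation raise explicit errors rather
  than returning divergent coefficients.
- The pooled (two-sex) confusion table defaults to the pooled Youden
  cutoff; whether published pooled tables use pooled or sex-specific
  cutoffs is typically ambiguous, so `pooled_rule = "sex_specific"` is
  available and the report states which rule produced the table.
- Cutoffs are reported unrounded; presentation rounding (one decimal for
  percentages, two for ratios and J) happens only in the rendered report,
  never in the CSV exports.
- The design-stage Buderer sample-size arms use the exact normal quantile;
  with anticipated sensitivity 95.2%, specificity 89.9%, prevalence 13.9%,
  5% margin, design effect 1.5 and 10% non-response the final size computes
  to 835. Published protocol numbers derived from the same inputs sometimes
  state 877; the formula's value is reported as computed and the
  discrepancy left to the reader, not silently reconciled.
- Report determinism: the same input and config reproduce the bundle
  byte-for-byte; the test suite pins the default-seed rendering against a
  committed golden file.

# Problem sizes used by the test suite

The suite exercises the estimators against brute-force oracles on hundreds
of small random instances, runs the full pipeline on the default 851-subject
cohort with 1000 bootstrap resamples, checks generator calibration at
n = 100,000, and estimates the Hosmer–Lemeshow null size from 400
simulated cohorts of n = 500. These sizes give Monte-Carlo error small
enough for the stated tolerances while keeping a full run in well under a
minute of compute.

# Known limitations

- The Gaussian-copula cohort cannot simultaneously match a pooled rank
  correlation of 0.81 and the AUC ≈ 0.96 seen in real adolescent data; the
  implied synthetic AUC is ≈ 0.93 because real MUAC–BMI dependence is
  stronger in the upper tail than a normal copula allows. Study-scale tests
  therefore assert the qualitative regime (AUC > 0.9, "excellent" band),
  not a point value.
- Clopper–Pearson intervals are conservative by construction; that is the
  accepted trade-off for exactness at small counts.
- No comparative-accuracy machinery (paired DeLong, McNemar) and no
  survey weighting; both are out of scope.
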