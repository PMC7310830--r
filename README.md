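# muacscreen

Diagnostic accuracy of mid-upper arm circumference (MUAC) as a screening
marker for overweight and obesity in adolescents.

## The problem

Identifying overweight in adolescents normally requires weight, height and a
growth-reference lookup to obtain a BMI-for-age Z-score. MUAC needs only a
tape measure, which makes it attractive for school- and community-level
screening in low-resource settings. `muacscreen` implements the full
statistical workflow for validating MUAC (or any continuous marker) against
a BMI-Z-score reference:

- **Anthropometric preprocessing** — replicate averaging with the field
  repeat rule (re-measure when two MUAC readings disagree by more than
  0.5 cm), BMI, LMS growth-reference Z-scores
  `z = ((x/M)^L − 1)/(L·S)` with the WHO restricted-tail adjustment beyond
  ±3 SD, technical error of measurement, and the WHO status convention
  (overweight including obesity: z > +1; obesity: z > +2).
- **Diagnostic metrics** — confusion tables under the `marker ≥ cutoff`
  screen-positive rule; sensitivity, specificity, PPV, NPV, accuracy,
  Youden's J = Se + Sp − 1, LR+ = Se/(1−Sp), LR− = (1−Se)/Sp; exact
  Clopper–Pearson intervals for proportions and Simel log-method intervals
  for likelihood ratios.
- **ROC analysis** — the empirical AUC as the Mann–Whitney rank statistic,
  DeLong structural-components confidence intervals, qualitative accuracy
  bands (excellent ≥ 0.9, good ≥ 0.8, …), and Youden-optimal cutoff
  selection by exhaustive search over observed values.
- **Internal validation** — bootstrap optimism correction of the AUC
  (refit-on-resample, test-on-original, 1000 resamples) and
  Hosmer–Lemeshow calibration with calibration slope/intercept for the
  univariable logistic model `logit P(overweight) = α + β·MUAC`.
- **Association** — Spearman rank correlation with the Fieller-corrected
  Fisher-z interval (SE = √(1.06/(n−3))).
- **Synthetic cohorts** — a Gaussian-copula generator reproducing the
  statistical structure of a two-sex adolescent cohort (per-sex marginals,
  a pooled rank-correlation target, replicate measurement noise, 0.1-unit
  instrument rounding), so the entire pipeline is testable without any
  subject-level data.

## Worked example

```r
library(muacscreen)

# a synthetic 851-subject cohort (456 male / 395 female)
cohort <- generate_cohort(cohort_spec(seed = 20200623))
report <- run_pipeline(cohort, pipeline_config(seed = 20200623, n_boot = 100))
print(report)
```

Key lines of the printed report (abridged):

```
-- Prevalence (BMI Z reference) --
overweight_only        55/851 = 6.5% (4.9-8.3)
obese                  17/851 = 2.0% (1.2-3.2)
overweight_incl_obese  72/851 = 8.5% (6.7-10.5)

-- Correlation (Spearman) --
MUAC ~ BMI Z: rho 0.80 (0.77-0.82), n=851

-- Discrimination (AUC, DeLong CI) --
total  AUC 0.94 (0.92-0.96), band excellent
male   AUC 0.96 (0.95-0.98), band excellent
female AUC 0.93 (0.91-0.96), band excellent
bootstrap optimism -0.0006 over 100 resamples (seed 20200623); corrected AUC 0.94
```

Reading it: 8.5% of this simulated cohort is overweight or obese by the
BMI-Z reference; MUAC correlates strongly with BMI Z (rho 0.80); MUAC
discriminates overweight from non-overweight with an AUC of 0.94 overall
(an "excellent" band), and the bootstrap finds essentially no optimism —
a univariable marker cannot meaningfully overfit. The panel section then
reports the Youden-optimal cutoff per stratum (here ≥ 28.05 cm pooled,
close to published adolescent cutoffs of 27.75–27.95 cm) with its full
metric panel.

Deterministic building blocks work directly from printed counts:

```r
summarize_confusion(confusion_table(tp = 112, fp = 71, fn = 11, tn = 657))
#> Diagnostic panel (n = 851)
#>       metric  point   lower   upper
#>  sensitivity 0.9106 0.84562  0.9545
#>  specificity 0.9025 0.87858  0.9230
#>          ppv 0.6120 0.53734  0.6830
#>          npv 0.9835 0.97073  0.9918
#>     accuracy 0.9036 0.88181  0.9226
#>     youden_j 0.8130      NA      NA
#>       lr_pos 9.3365 7.43449 11.7252
#>       lr_neg 0.0991 0.05635  0.1743
```

A thin command-line wrapper with `simulate`, `analyze` and `validate`
subcommands lives in `inst/cli/muacscreen.R`.

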