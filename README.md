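# ogttfda

Functional data analysis of oral glucose tolerance test (OGTT) glucose and
insulin curves, for biostatisticians and pediatric-metabolism researchers
studying dysglycemia risk in children and adolescents with overweight or
obesity.

A standard 2-hour OGTT samples plasma glucose and insulin at 0, 30, 60, 90
and 120 minutes. Single summary values (fasting glucose, 2-hour glucose,
HbA1c) ignore the *dynamics* of the response. This package treats each
participant's five-point series as a sampled smooth curve and provides:

1. **Penalized spline smoothing.** Each series is represented as
   `y_i(t) = Σₖ c_ik φ_k(t)`, with seven cubic B-spline basis functions
   built on knots at the measurement times, fitted by penalized least
   squares

   `ĉ_i = argmin_c ‖y_i − Φc‖² + λ cᵀRc`

   where `R` holds integrated products of second derivatives (a curvature
   penalty). One `λ` per analyte is chosen by leave-one-point-out
   cross-validation pooled across the cohort.

2. **Functional principal component analysis (FPCA).** The cohort's
   covariance operator is decomposed into orthonormal eigenfunctions `ξ_k`
   (`∫ξ_k² dt = 1`, `∫ξ_j ξ_k dt = 0`); each curve gets three scores
   `z_ik = ∫ ξ_k(t) (y_i(t) − ȳ(t)) dt`, standardized to mean 0 / SD 1.
   On realistic cohorts FPC1 tracks overall curve height, FPC2 the timing
   of the peak, FPC3 oscillation, and three components explain over 99% of
   curve variance.

3. **Curve-shape classification.** The classical manual rules on the raw
   glucose series with a 4.5 mg/dL threshold: *biphasic* (peak, drop ≥ 4.5,
   re-rise ≥ 4.5), *monophasic* (peak, drop ≥ 4.5, no qualifying re-rise),
   *monotonically increasing* (never drops more than 4.5 below the running
   maximum), *inconclusive* (no rise above fasting by 60 min).

4. **Association testing.** Spearman correlations of shape dummies and the
   six standardized FPC scores against timed glucose/insulin values and
   metabolic labs, Bonferroni-controlled over the planned 171 comparisons
   (p < 0.05/171 ≈ 0.0003); Kruskal–Wallis / Fisher's exact tests across
   shape classes; linear models adjusted for age, sex, race and ethnicity.

5. **Dysglycemia prediction.** Dysglycemia = fasting glucose > 100 mg/dL
   or 2-h glucose > 140 mg/dL. Seven baseline predictor sets — FPG, 2hrPG,
   HbA1c, shape dummies, glucose FPCs, insulin FPCs, glucose+insulin FPCs
   — are compared by logistic regression and in-sample ROC/AUC on the
   longitudinal subset (follow-up ≥ 6 months), plus paired Wilcoxon and
   McNemar change tests.

6. **Synthetic cohorts.** Because real OGTT cohorts of this kind are
   restricted, a seeded generator produces cohorts with the structure the
   analysis assumes: archetype mixture 54.7% monophasic / 42.0% biphasic /
   2.5% monotonic / 0.8% flat, fasting glucose ~ N(83, 8), labs positively
   linked to curve height, 28.8% follow-up, ~7.3% follow-up dysglycemia
   driven by latent curve height and 120-min excursion (and deliberately
   *not* by fasting glucose).

## Worked example

```r
library(ogttfda)
res <- run_pipeline(ogtt_config(seed = 1), n = 500, verbose = FALSE)
print(res)
```

```
OGTT pipeline results: 500 participants
  lambda: glucose 4642, insulin 0.0001
  glucose FPCs explain 78.59 / 16.62 /  4.12% (total 99.32%)
  insulin FPCs explain 87.32 / 10.62 /  1.33% (total 99.27%)
  shapes: biphasic 205, monophasic 271, monotonically_increasing 21, inconclusive 3
Dysglycemia prediction, seven predictor sets (in-sample AUC):
  glucose+insulin FPCs   AUC = 0.812  (n = 146, events = 13)
  glucose FPCs           AUC = 0.760  (n = 146, events = 13)
  insulin FPCs           AUC = 0.721  (n = 146, events = 13)
  2hrPG                  AUC = 0.693  (n = 146, events = 13)
  HbA1c                  AUC = 0.660  (n = 146, events = 13)
  shape                  AUC = 0.573  (n = 145, events = 13)
  FPG                    AUC = 0.432  (n = 146, events = 13)
```

Reading this: the two cross-validated smoothing parameters are shared by
all participants (one per analyte); three FPCs capture >99% of the
variance in both analytes; the shape mixture matches the generator's
archetype weights; and on the 146-participant longitudinal subset with 13
dysglycemia events, the combined glucose+insulin FPC scores rank future
dysglycemia best (AUC 0.81) while fasting glucose — uninformative by
construction in the generator — hovers at chance.

Classify a single profile:

```r
classify_shape(c(85, 130, 110, 125, 120))
#> OGTT shape: biphasic (peak at point 2, drop 20.0, re-rise 15.0)
```

A command-line wrapper lives at `inst/scripts/ogttfda.R`
(`simulate` and `run` subcommands).

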