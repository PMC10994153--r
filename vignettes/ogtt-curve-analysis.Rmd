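---
title: "Methods: penalized smoothing, FPCA and risk prediction for OGTT curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized smoothing, FPCA and risk prediction for OGTT curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogttfda)
```

This vignette documents the statistical model behind `ogttfda`, the choices
made where the methodology was genuinely open, the numerical conventions,
and what the synthetic-data generator does and does not emulate.

## The smoothing model

A 2-hour OGTT yields five measurements per analyte at t = 0, 30, 60, 90,
120 minutes. Each participant-analyte series is modelled as a smooth curve
in a cubic (order-4) B-spline basis whose knots sit at the measurement
times. Three interior knots plus order four give exactly seven basis
functions, so the representation is

$$y_i(t) = \sum_{k=1}^{7} c_{ik}\,\phi_k(t),$$

and coefficients are estimated by penalized least squares,

$$\hat c_i = \arg\min_c\; \lVert y_i - \Phi c\rVert^2
  + \lambda\, c^\top R\, c ,
  \qquad R_{jk} = \int_0^{120} \phi_j''(t)\,\phi_k''(t)\,dt .$$

The curvature penalty leaves constants and straight lines untouched
(`c^T R c = 0` for any linear function), and for every λ > 0 the system
`Φ'Φ + λR` is positive definite because no nonzero linear function
vanishes at all five knots. Consequences that the tests rely on: constant
and linear series are reproduced *exactly* at every λ, residual sum of
squares is nondecreasing and roughness nonincreasing in λ, and as
λ → ∞ the fit converges to the ordinary least-squares line.

**Choosing λ.** The smoothing parameter is shared by all participants,
one value per analyte. The package uses leave-one-point-out
cross-validation pooled over the cohort: for each candidate λ and each of
the five time points, the curve is refit from the other four points and
the held-out measurement predicted. Because the measurement schedule is
common, the held-out predictor is a fixed linear functional of the
retained points, precomputed once per (λ, point). Generalized
cross-validation would be a reasonable alternative; plain point-deletion
CV was chosen because it is the most literal reading of "cross-validation"
for curves observed at shared time points, and the selected λ is recorded
in the run manifest. The default grid is 25 log-spaced values on
10⁻⁴…10⁴ (unitless, multiplying a penalty in (mg/dL)²/min³).

Two degenerate paths are explicit rather than accidental:

* **λ = 0** leaves 5 equations with 7 unknowns; `fit_curve()` returns the
  minimum-norm least-squares solution and warns. It is never on the
  default path.
* **A flat CV profile** (e.g. a cohort of straight lines, which every λ
  reproduces) is detected by comparing the CV spread against the squared
  data scale (relative tolerance 10⁻⁸); the largest grid value is then
  returned and flagged, since maximal smoothing costs nothing. Exact ties
  otherwise resolve to the smallest λ.

Numerical note: at λ ≳ 10⁶ the normal-equations matrix is ill-conditioned
and penalty-free directions (lines) can drift at the 10⁻⁶ level; one step
of iterative refinement restores the exact-reproduction property to below
10⁻⁸, which the tests assert.

## Functional principal components

Let `J` be the Gram matrix of integrated basis products and `S` the sample
covariance of the fitted coefficient vectors (mean-centred, denominator
n − 1). Eigenfunctions of the covariance operator are obtained from the
symmetric eigenproblem of `J^{1/2} S J^{1/2}`: with eigenvectors `u_k`,
the eigenfunction coefficients are `b_k = J^{-1/2} u_k`, which enforces
`∫ξ_k² = 1` and pairwise orthogonality exactly. Eigenvalues equal the
variances of the scores

$$z_{ik} = \int_0^{120} \xi_k(t)\,\bigl(y_i(t) - \bar y(t)\bigr)\,dt,$$

and variance-explained fractions are taken over the full spectrum of the
operator. All integrals use composite-trapezoid quadrature on a 1-minute
grid (121 points; the step is configurable). Because fitted curves live in
the 7-dimensional basis span, this coefficient-space route agrees with a
brute-force eigendecomposition of the grid-discretized covariance to
near machine precision — the test suite checks |cosine| ≥ 0.999 and
eigenvalue relative error ≤ 10⁻⁴ over 50 random cohorts.

Three retained components follow functional-data practice for OGTT
curves; the count is a config constant (`n_fpc`), not data-adaptive.

**Centering.** Scores are computed against the cohort mean curve. An
uncentred inner product would shift every participant's score by the same
constant, which the subsequent standardization (mean 0, SD 1 with
denominator n − 1) erases, so downstream statistics are identical either
way; centring makes the raw scores interpretable as deviations.

**Sign convention.** Eigenfunctions are sign-ambiguous, so each ξ_k is
flipped to make `∫ξ_k dt ≥ 0`, falling back to `ξ_k(0) > 0` when the
integral is within 10⁻⁹ of zero. This makes runs reproducible across
platforms and keeps "higher FPC1 = higher curve" on realistic cohorts.

**Degenerate inputs.** Fewer curves than components + 1, or a cohort of
identical curves (zero covariance operator), are errors naming the
condition; a zero-variance component likewise blocks standardization.

Quartile summaries (`quartile_curves()`) bin participants per component
with ties assigned to the lower bin, and a decile variant returns the
bottom/top 10% mean curves.

## Shape classification

The rules operate on the *raw* five glucose measurements — manual
classification in the clinical literature is done on observed profiles,
not smoothed ones — with threshold δ = 4.5 mg/dL, applied in a fixed
order:

1. *inconclusive*: no rise above the 0-min value at 30 or 60 min;
2. *monotonically increasing*: no point more than δ below the running
   maximum ("more than" read strictly, so a drop of exactly 4.5 still
   counts as monotone);
3. *biphasic*: an initial peak, a drop ≥ δ, then a rise ≥ δ from the
   post-drop minimum ("at least" read inclusively);
4. *monophasic*: a drop ≥ δ after the maximum and no qualifying re-rise.

The published rule set does not state a precedence; this order makes the
four classes mutually exclusive and exhaustive, and the classifier stores
its evidence (peak index, drop, re-rise) so boundary decisions are
auditable. Plateaus (equal consecutive values) count as neither rise nor
drop. Raising δ can only move a profile along biphasic → monophasic →
monotonically increasing — verified by enumeration over an exhaustive
small-integer profile lattice. For modelling, shapes are coded as
dichotomous dummies; inconclusive profiles carry no class and are dropped
from shape-coded analyses with a logged count.

## Association battery

Spearman correlations (average-rank ties) are computed per pair on
complete cases, reflecting variable-specific missingness; p-values are
exact for n ≤ 10 without ties and t-approximated otherwise. The
Bonferroni divisor defaults to the planned inventory of 171 = 9 × 19
comparisons: 9 features (3 shape dummies + 3 glucose FPCs + 3 insulin
FPCs) against 19 targets (10 timed glucose/insulin values, HbA1c, four
lipids, systolic/diastolic blood pressure, BMI percentile, waist
circumference). It is a config constant rather than recomputed, so users
who test fewer pairs retain the planned control. Kruskal–Wallis handles
continuous variables across shape classes and Fisher's exact test
categorical ones (degenerate single-level tables return NA rather than
aborting a pipeline run). Adjusted models are ordinary least squares,
`FPC ~ exposure + age + sex + race + ethnicity`, with rank deficiency an
error naming the aliased term; the pipeline may drop a factor covariate
that has a single observed level in a small cohort, and logs nothing
silently.

## Longitudinal prediction

Dysglycemia is the composite `FPG > 100 mg/dL or 2hrPG > 140 mg/dL`, with
strict inequalities — values exactly at a threshold are negative. The
longitudinal subset requires a follow-up at least 6 months after
baseline; shorter intervals are excluded and logged. Paired change tests
use the Wilcoxon signed-rank statistic (identical pairs yield statistic 0
and p = 1 rather than an error) and McNemar's test for the dysglycemia
rate, computed as the exact binomial on discordant pairs when fewer than
25 are discordant — so balanced 10-vs-10 discordance gives p = 1
exactly — and the uncorrected chi-square form otherwise.

Seven predictor sets are compared: FPG, 2hrPG, HbA1c, shape dummies
(biphasic and monotonically-increasing against a monophasic reference, to
avoid collinearity), glucose FPCs, insulin FPCs, and both FPC triplets.
Fits are unpenalized maximum likelihood, evaluated *in sample* — with
event counts around 14 a train/test split is not viable, and that is the
design regime this package targets. Complete separation and
non-convergence are detected and flagged, never hidden; the AUC of a
separating score is still well-defined and reported.

AUC is the Mann–Whitney concordance (ties 1/2), computed from average
ranks, with the ROC staircase built by threshold sweep. Two ranking
conventions coexist deliberately:

* multi-variable sets are ranked by the fitted probability;
* single-variable sets are ranked by the raw marker in its conventional
  clinical direction (higher value = riskier). This equals the
  fitted-probability ranking whenever the ML slope is positive, and it
  avoids the sign-fitting fold of in-sample fits: at ~14 events the ML
  sign choice alone inflates the null median AUC to roughly 0.56, which
  would misrepresent an uninformative marker.

Relatedly, the in-sample AUC of a k-predictor null fit is optimistic by
approximately `pnorm(sqrt(k(1/n₁+1/n₀))/sqrt(2)) − 0.5`; the test suite
checks fitted models against that expectation rather than pretending
in-sample fits are unbiased.

## The synthetic cohort generator

The generator exists so that every stage is testable without restricted
clinical data. It emulates:

* four glucose archetypes — monophasic (peak at 60 min), biphasic (peak
  at 30, dip ≥ 4.5, re-rise ≥ 4.5), monotonically increasing, and flat
  (feeding the inconclusive path) — as natural cubic splines through five
  control values, mixed at 54.7 / 42.0 / 2.5 / 0.8%; each archetype's
  noise-free series triggers exactly its own classifier rule for any
  amplitude ≥ 20 mg/dL;
* fasting glucose N(83, 8) mg/dL (floored at 55), glucose measurement
  noise SD 4 mg/dL (a typical plasma-assay scale) truncated at a
  40 mg/dL physiological floor;
* insulin as gain × (basal + delayed glucose excursion + noise), delayed
  15 min, floored at 1 μU/mL; the pre-floor values are exactly
  proportional to the gain, which links insulin height to BMI percentile.
  No public summary statistics exist for the insulin scale in this
  population, so the basal median (8), gain (median 1.5) and noise (SD 3
  pre-gain units) are free calibration choices, documented here;
* demographics at the target margins (53.9% female; 57.5/31.6/7.8/3.1%
  white/Black/other/unknown; 5.8% Hispanic; ages uniform 8–18; BMI
  percentile concentrated near the 97th via a beta transform);
* metabolic labs (HbA1c, lipids, blood pressure, waist) as linear or
  log-linear functions of the latent curve excursion plus noise, with
  coefficients placed so that curve-height correlations land in the
  0.15–0.5 band typical of such cohorts — calibration targets, not ground
  truth;
* variable-specific missingness (BP 3.1%, waist 3.6%, lipids 1.5%);
* follow-up for 28.8% of participants, interval log-normal around 14
  months (intervals under 6 months occur and are excluded downstream, as
  in a real analysis), and follow-up dysglycemia whose log-odds are
  linear in the standardized latent curve excursion and the 120-min
  excursion above fasting, with the intercept calibrated so the mean
  event probability equals 7.3%. The drivers deliberately exclude fasting
  glucose, so the FPG predictor is uninformative by construction; the
  120-min *excursion* (rather than the raw 120-min value, which contains
  fasting glucose) keeps that property exact.

Each participant draws from a private RNG substream derived from the
master seed, so enlarging a cohort leaves existing participants
unchanged.

**What it does not emulate.** Pubertal stage and its insulin-resistance
physiology; assay-specific error structure; within-person visit-to-visit
reproducibility; differential follow-up by health status; any joint
demographic structure beyond the stated margins; and real glucose–insulin
mechanistic coupling (the gain-and-delay transform is phenomenological,
not an ODE model). Passing tests therefore demonstrate that the
*machinery* — smoothing, FPCA, classification, testing, prediction —
behaves correctly under the assumed structure, not that any particular
clinical effect size generalizes.

## Problem sizes and runtime choices

The test suite exercises: variance capture and score standardization on
n = 500 and n = 120 cohorts; FPCA oracle equivalence on 50 random
cohorts of 15–50 curves; planted-component recovery at n = 500 with
eigenvalue ratio 10:3:1; the shape lattice at 5⁵ profiles × 4 thresholds;
null calibration of Kruskal–Wallis and the adjusted models at 400–1000
replicates; and the predictor-ordering experiment at 500 replicates of
n = 200 all-follow-up cohorts (~14 events each), chosen to mirror the
event count the method is designed around while keeping a single-CPU run
in the low minutes.

## Known limitations

* λ is selected on a finite grid; no continuous optimization.
* FPCA assumes the presmoothed curves are the objects of interest;
  smoothing-induced bias at the 5-point design is not corrected
  (no regularized/sparse-design FPCA).
* The seven-predictor comparison reports in-sample AUC without
  confidence intervals or DeLong tests, matching its design regime;
  optional k-fold evaluation is a possible extension.
* Glucose and insulin are decomposed separately; no bivariate FPCA.
* The generator's effect sizes are calibration choices; association
  magnitudes on synthetic data should not be quoted as clinical findings.
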