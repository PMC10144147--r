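---
title: "Modeling bivariate age trajectories of fluid cognition and functional limitation"
author: "bivtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bivariate age trajectories of fluid cognition and functional limitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bivtraj)
```

## The problem and the two-stage design

Population panels like the Health and Retirement Study assess adults every
two years, but scientific interest is in change along *chronological age*:
how fast does general fluid cognition decline, how fast do functional
limitations accumulate, and how are the two coupled in middle versus later
adulthood?  With only three waves per person but baseline ages spanning
50–85, an accelerated longitudinal design covers the full age range by
pooling: each person contributes a short age segment, and the model splices
the segments into population trajectories.

`bivtraj` implements this as a two-stage procedure:

1. **Measurement stage.** A bivariate longitudinal confirmatory factor
   model summarizes four cognitive items and three functional-limitation
   items as two correlated factors per wave.  Strong factorial invariance
   (equal loadings *and* item intercepts across waves) is imposed so that
   latent change over time is interpretable; items are first standardized
   to their wave-1 mean and SD so the factors share one metric.  Person-wave
   factor scores are extracted with Bartlett's estimator, which is
   conditionally unbiased for the latent state and uses whatever indicators
   a person actually answered.
2. **Growth stage.** Scores are placed in two-year age bins (50/51 …
   84/85; 18 bins), rescaled to the mean/SD of the 70/71 bin, and modeled
   with latent trajectory models whose fixed loadings encode time in
   *decades centered at age 70*: intercept-only, linear, and piecewise
   ("spline") parameterizations with two slopes meeting at a knot bin.
   The bivariate model couples the processes through a full latent
   covariance and a single within-bin residual covariance.

The estimand hierarchy mirrors how results are read: slope means are
average change per decade in age-70 SD units; latent variances quantify
between-person heterogeneity in change; latent correlations express
coupling (e.g., between mid-life cognitive slope and the limitation
slope); cumulative change multiplies slopes by the window widths (2.0
decades for 50→70, 1.5 for 70→85).

## The estimation engine

All models are instances of one linear moment structure
$\mu = \nu + \Lambda\alpha$, $\Sigma = \Lambda\Psi\Lambda' + \Theta$,
fitted by casewise full-information maximum likelihood: each person
contributes the normal log-density of their observed sub-vector, so
monotone attrition and arbitrarily sparse bin patterns are handled without
imputation, and the estimates are valid under missingness at random.
Design choices that matter:

* **Unconstrained reparameterization.** Variances are optimized as
  log-SDs and free latent covariance blocks as log-Cholesky factors, so
  quasi-Newton iteration (`nlminb`, analytic gradients, BFGS polishing)
  never leaves the feasible cone.  Equality constraints (invariance
  classes, homogeneous residuals) are index maps: one free parameter, many
  cells.
* **Convergence is a verdict, not an assumption.** A fit is `converged`
  only if the per-case gradient norm falls below 1e-5 and the observed
  information is positive definite; anything else is reported as
  non-converged, and the pipeline's comparison tables carry a convergence
  column because model selection hinges on it.
* **Standard errors.** Naive SEs invert the observed information
  (numerically differentiated analytic gradients, central differences,
  step 1e-4 scaled); robust SEs are the Huber–White sandwich
  $A^{-1}BA^{-1}$ with $B$ the casewise score outer-product sum.  Setting
  $B = A$ reproduces the naive SEs exactly, which the tests assert.
  Natural-scale estimates (variances, correlations) and their SEs come
  from the delta method.  Wald p-values are flagged at α = 0.005, a
  conservatism appropriate to panel-scale n.
* **Fit statistics.** The saturated (unrestricted μ, Σ) log-likelihood is
  maximized by EM on missing-data patterns; χ² = 2(sat − model), df =
  (all first and second moments) − (free parameters).  The TLI baseline is
  the independence model (free means and variances, zero covariances),
  which under FIML factors per variable and is available in closed form.
  RMSEA uses the number of analysis cases n (not n − 1) — a convention
  pinned by back-calculating a published fit row — and its 95 % CI inverts
  the noncentral χ² at probabilities .975/.025.
* **EM details.** The EM is SQUAREM-accelerated (two EM steps plus a
  monotonicity-guarded extrapolation) and runs on internally standardized
  columns, which makes its path exactly equivariant under per-column
  affine rescaling — hence `rescale_at_bin` provably leaves χ², TLI and
  RMSEA unchanged (asserted to 1e-6).  With extremely sparse columns (a
  bin observed once) the saturated likelihood is unbounded; a variance
  floor of 1e-6 times the mean variance plus an escalating ridge keeps the
  EM defined, and the result is flagged `ridged`.  Convergence is a
  relative log-likelihood change below 1e-9 (default cap 5000 steps).
* **Degenerate inputs.** Structures with more parameters than sample
  moments are refused; all-missing rows and never-observed columns are
  excluded with logged counts; a singular sandwich A-matrix triggers a
  warning, a condition-number report, and a pseudo-inverse rather than a
  crash.

## What the synthetic generator emulates — and what it does not

The generator's defaults *are* the study conditions the pipeline targets.
The bivariate growth configuration uses the fitted bivariate model's
means, variances, correlations and residuals; the univariate
configurations use the univariate spline estimates.  The panel design
draws baseline ages from N(64.9, 9.6) truncated to [50, 83] — truncated
so that all three waves (+0/+2/+6 years) can land inside the 50–85
modeling window — and reports them in whole years, as survey age
variables are recorded; rounding also keeps the generated age resolution
(1 year) finer than the bin width (2 years), without which the lower-edge
bin codes would systematically displace intercept means by about a tenth
of a decade times the slope.  Cumulative retention defaults to
1/.916/.752, matching the panel's wave counts, with monotone dropout that
is logistic in current functional limitation (log-odds 0.3 per score
unit): missingness at random on an observed-system variable, which is
exactly the mechanism FIML claims to handle and therefore the one worth
stress-testing.  Setting the coefficient to 0 gives completely-at-random
attrition.

Item-level generation is linear in the person-wave factor state (the
trajectory value plus an occasion disturbance with the configured residual
SDs and the single cross-process residual correlation), with
censored-count items rounded and clipped to their score ranges.  The
floor-censoring of the limitation items produces the positive skew seen in
such self-reports (ADL means near 0.3 with skewness above 2).  The
measurement defaults were calibrated by simulation so the *fitted*
standardized loadings reproduce the published pattern (numeracy ≈ .85 down
to recall ≈ .445; ADL ≈ .82, IADL ≈ .578) together with wave-1 item means
and SDs; the calibrated values are frozen in
`measurement_config()`.

What passing tests on these panels do **not** show about real data: the
generator's measurement model is linear-with-censoring, so it cannot
expose bias from genuinely ordinal items (the real analysis treats them as
continuous too, a known approximation); attrition depends only on current
latent limitation, not on health shocks or mortality; ages are exact and
retest effects, cohort effects, and survey weights are absent by design.
Recovery results certify the *pipeline arithmetic* under its own
assumptions, not the substantive correctness of those assumptions.

## Univariate generating values the sources do not pin down

The univariate spline reports print slope means and all variances but no
intercept mean, no residual variance, and no coefficient correlations.
The package's univariate defaults therefore set the intercept mean to 0
(scores are standardized at the 70/71 bin, so the intercept mean is a
free location), reuse the bivariate residual variances (.313/.475), and
borrow the bivariate within-process correlation pattern (for the
limitation spline, the intercept–slope correlation .429 is applied to
both slopes, with .154 between slopes).  Slope-mean recovery — the tested
quantity — is insensitive to these fill-ins; they only shape the
nuisance covariance.

## Numerical and structural conventions

* **Bin time codes** use the lower bin edge, $s_b = (\text{lower} - 70)/10$,
  so bin 70/71 is exactly the zero point and the knot sits at the code
  origin.  With 2-year bins this convention leaves a small residual
  discretization offset (in-bin mean age exceeds the lower edge by about
  half a year under integer ages); its remaining effect on recovered
  parameters is below 0.01 on slope means and within the recovery bands
  asserted by the tests.
* **Scoring is per wave**, jointly over the wave's two factors, never
  across waves: smoothing scores longitudinally would leak information
  into the growth stage and bias its covariance estimates.  Because items
  load on a single factor and residuals are diagonal, the joint
  information matrix is block-diagonal and a factor with no observed
  indicator simply yields a missing score.
* **Marker identification** (first item per process fixed to loading 1;
  wave-1 latent means fixed to 0) is the default; standardized loadings
  are computed post hoc and are invariant to the identification choice
  (asserted to 1e-4 against unit-variance scaling).  A consequence worth
  knowing: Bartlett scores estimate the latent state *relative to the
  wave-1 factor mean*, a constant offset that cancels in all growth-stage
  quantities except the intercept mean's absolute location — and the
  rescaling at bin 70/71 re-anchors that anyway.
* **Duplicate occasions in one bin** (possible when flooring ages) are
  averaged rather than dropped, keeping one observation per manifest
  variable.
* **Model comparison** tabulates χ²(df), TLI, RMSEA [95 % CI], AIC and
  convergence, computes Δχ²/Δdf for consecutively nested models, selects
  by lowest AIC *among converged candidates*, and refuses to compare fits
  whose data fingerprints differ.

## Problem sizes used by the test suite

The suite exercises every stage at sizes chosen to make Monte-Carlo error
small relative to the asserted bands while keeping a laptop-scale run:
coefficient-moment checks at n = 50,000–100,000 draws; factor-model
recovery and Bartlett unbiasedness at n = 20,000 persons; trajectory
recovery at the study-scale n = 3,000 with 10–40 seeded replicates
(slope means within ±0.02, correlations within ±0.10); robust-SE coverage
with 500 replicates of a small n = 200 growth model (93–97 % band); and
full pipeline runs at n = 250–300 for artifact and determinism checks.

## Known limitations

* The two-stage procedure ignores factor-score estimation error in stage
  2; the occasion residual absorbs it, which slightly inflates residual
  variances and attenuates occasion-level coupling relative to a
  one-stage model.  This matches the published procedure; a
  measurement-error-corrected stage 2 is out of scope.
* Spline models with knots far from the data's center (60/61, 74/75) can
  converge on clean synthetic data even where real data defeat them;
  convergence flags are reported per candidate rather than assumed to
  replicate any particular real-data pattern.
* Saturated-model χ² with 36 sparsely observed manifests rests on many
  weakly identified moments; at moderate n the model χ² can fall below
  its nominal df (TLI > 1, RMSEA = 0).  The comparison columns remain
  interpretable because all candidates share the same saturated anchor.
* No survey weights, no retest-effect adjustment, no covariates, no
  modeling beyond age 85.
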