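# bivtraj

Two-stage structural equation modeling of age-related change in **general
fluid cognition** and **functional limitation** for accelerated longitudinal
panels such as the Health and Retirement Study (HRS): a longitudinal factor
model with strong invariance and Bartlett factor scores (stage 1), followed
by age-binned univariate and bivariate piecewise-linear latent trajectory
models estimated by casewise full-information maximum likelihood (FIML)
with Huber–White robust standard errors (stage 2).  The package is aimed at
aging and epidemiology researchers who want to model change on
*chronological age* rather than time-in-study, and at methodologists who
need a transparent, fully testable FIML engine with known-truth synthetic
panels.

## The model

**Stage 1 (measurement).** At each wave *t*, four cognitive items
(numeracy W-score, category fluency, serial-7s, word recall) and three
functional-limitation items (mobility 0–11, ADL 0–6, IADL 0–5) measure two
correlated factors,

&nbsp;&nbsp;&nbsp;&nbsp;*y*<sub>jt</sub> = ν<sub>j</sub> + λ<sub>j</sub> η<sub>t</sub> + ε<sub>jt</sub>,

with loadings λ<sub>j</sub> and intercepts ν<sub>j</sub> constrained equal
across waves (strong factorial invariance), items standardized to the
first-wave mean and SD, and factor scores extracted by Bartlett's
weighted-least-squares estimator
(Λ′Θ<sup>−1</sup>Λ)<sup>−1</sup>Λ′Θ<sup>−1</sup>(y − ν) over each
person-wave's observed indicators.

**Stage 2 (growth).** Scores are placed in two-year age bins 50/51 … 84/85
and rescaled at bin 70/71.  With the decade time code
*s* = (bin − 70)/10, the bivariate model is

&nbsp;&nbsp;&nbsp;&nbsp;COG<sub>b</sub> = COG<sub>i</sub> + COG<sub>s1</sub>·min(*s*,0) + COG<sub>s2</sub>·max(*s*,0) + ε<sub>C</sub>,<br>
&nbsp;&nbsp;&nbsp;&nbsp;FNC<sub>b</sub> = FNC<sub>i</sub> + FNC<sub>s</sub>·*s* + ε<sub>F</sub>,

i.e. a piecewise (spline) slope for cognition with a knot at age 70 and a
single linear slope for limitation, a free 5×5 latent covariance,
homogeneous per-process residual variances, and one within-bin
cross-process residual covariance.  Everything is estimated by FIML over
missing-data patterns (each person observes at most 3 of 18 bins), with
model χ² against an EM-fitted saturated model, TLI, RMSEA with a
noncentral-χ² 95 % CI, AIC, and sandwich (Huber–White) standard errors.

A synthetic-data module generates item- and score-level panels with the
same structure (truncated-normal baseline ages, waves at +0/+2/+6 years,
monotone and optionally MAR attrition calibrated to the HRS wave counts,
floor-censored limitation counts with realistic positive skew), so every
stage of the pipeline is testable against known ground truth.

## Worked example

Simulate a factor-score panel from the default bivariate configuration,
bin it by age, and fit the bivariate spline+linear model:

```r
library(bivtraj)
des  <- panel_design(n_persons = 3000, retention = c(1, 1, 1),
                     mar_attrition_coef = 0, seed = 2024)
sim  <- generate_score_panel(growth_config(), des)
bins <- assign_age_bins(sim$panel)
fit  <- fit_bivariate_trajectory(bins, se = "robust", h1 = TRUE)
print(fit)
fit$params[fit$params$type == "mean", ]
fit$cumulative_change
```

```
FIML fit: 3000 cases, 23 free parameters
  logLik = -22495.832   AIC = 45037.7   converged: TRUE (|grad| = 3.86e-06)
  Chi2(679) = 275.5   TLI = 1.056   RMSEA = 0.000 [0.000, 0.000]
     parameter type estimate se_naive se_robust    z       p sig
1  mean(COG_i) mean    0.031    0.023     0.023  1.4 1.7e-01
2 mean(COG_s1) mean   -0.045    0.024     0.024 -1.9 6.0e-02
3 mean(COG_s2) mean   -0.226    0.034     0.034 -6.8 1.5e-11   *
4  mean(FNC_i) mean    0.111    0.019     0.019  5.8 5.2e-09   *
5  mean(FNC_s) mean    0.218    0.019     0.019 11.4 5.8e-30   *
  process window change
1     COG  50-70  -0.09
2     COG  70-85  -0.34
3     FNC  50-70   0.44
4     FNC  70-85   0.33
```

The slope means are per decade in age-70 SD units: cognition declines by
−0.045 SD/decade before age 70 and −0.226 SD/decade after, limitation
rises by 0.218 SD/decade, and the estimates recover the generating
configuration (−0.047, −0.230, 0.229) to sampling precision.
`cumulative_change` converts the slopes to total change over ages 50–70
(2.0 decades) and 70–85 (1.5 decades).  Significance stars use α = 0.005.
At n = 3000 the model χ² falls below its 679 df (most of the 702 saturated
moments are weakly identified from ≤ 3 observed bins per person), so the
TLI exceeds 1 and RMSEA is 0 — expected for a correctly specified model at
this size.

The full item-level pipeline (simulate → screen → standardize → factor
model → Bartlett scores → bins → trajectory model set → comparison tables
and a run manifest) is one call:

```r
res <- run_pipeline(pipeline_config(design = panel_design(n_persons = 2000),
                                    out_dir = "out", seed = 1))
```

or from a shell, `Rscript inst/scripts/bivtraj-pipeline.R run --n 2000
--seed 1 --out out` (verbs `simulate`, `fit-lfa`, `scores`,
`fit-trajectory`, `run`; `--dump-config` prints the generator defaults).

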