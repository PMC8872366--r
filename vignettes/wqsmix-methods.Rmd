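---
title: "Methods: stratified-interaction WQS regression, g-computation and reduction scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified-interaction WQS regression, g-computation and reduction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqsmix)
```

## The problem

Pregnant women are exposed to dozens of endocrine-disrupting chemicals (EDCs)
at once.  Single-chemical regressions misrepresent this reality: exposures are
correlated within chemical families, individual coefficients suffer from
collinearity and reversal artifacts, and the health-relevant quantity is the
joint action of the mixture.  `wqsmix` estimates a single empirically weighted
index of 26 prenatal EDC biomarkers (phenols, plasticizer metabolites, other
short-lived compounds, PFAS, persistent chlorinated compounds) and relates it
to a continuous child outcome (7-year full-scale IQ), allowing the weights and
the slope to differ by child sex.  The fitted index then serves as the
exposure *metric* in two further analyses: g-computation of marginal
counterfactual effects, and arithmetic "what if we reduced exposure" policy
scenarios.

## The model

Concentrations are preprocessed (creatinine adjustment of urinary analytes,
molar/plain sums of metabolite panels, a 75%-detection filter with summed
variables exempt) and each chemical is scored into deciles 0–9 on the full
cohort.  The outcome model is the stratified interaction parameterization

$$y_i = \beta_0 + \beta_1 \mathrm{WQS}_i + \beta_2 x_i +
  \beta_{12} x_i \mathrm{WQS}_i + \varphi' z_i + \varepsilon_i,$$

where $x_i$ indicates girls, $z_i$ are the covariates (nutrition index,
energy, maternal age, weight, education, Raven IQ, smoking) and

$$\mathrm{WQS}_i = \sum_{j=1}^{26} w_{s(i),j}\, q_{ij}$$

uses only the weight block of subject $i$'s sex stratum $s(i)$.  The 52
weights are nonnegative and sum to one, so that $1/52 \approx 0.019$ — the
value every weight takes in an equi-weighted index — is the natural guideline
for flagging chemicals of concern.  Boys are the reference stratum: their
slope is $\beta_1$ (sign-constrained, here negative for an adverse mixture)
and the girls' slope is reported as $\beta_1 + \beta_{12}$, never as a free
parameter.

### Identifiability and the half-mass block constraint

A design choice worth spelling out.  If the 52 weights were free on a joint
simplex, the *split of total mass between the two sex blocks would not be
identified*: for any reallocation of mass between blocks, rescaling $\beta_1$
and $\beta_{12}$ reproduces the identical fit, because each stratum's
likelihood depends only on the product of its slope with its block mass.  The
optimizer's block split — and with it the magnitude of $\beta_1$ — would be an
initialization artifact.  `wqsmix` therefore fixes each sex block at mass
$1/2$ (one 52-weight vector summing to 1, softmax-parameterized per block).
This keeps the $1/52$ equi-weight guideline exact while making the slope
magnitudes well defined.  One visible consequence: when all the signal sits on
a single chemical, its weight converges to the block maximum $0.5$ (with
within-block share $\to 1$), and the per-decile effect of that chemical is the
identified product $\beta_1 w$.

### Estimation

Estimation follows the two-step bootstrap-ensemble scheme:

1. On a bootstrap resample of the training data, minimize the residual sum of
   squares jointly over the weights and coefficients, with $\beta_1$
   sign-constrained.  Weights enter through per-block softmax logits; given
   the weights and $\beta_1$, the remaining coefficients are linear and
   profiled out by least squares, so the optimizer works on a 53-parameter
   profiled objective with an analytic gradient (envelope theorem), compiled
   in C++.  The solver is `optim(method = "L-BFGS-B")` — the box constraint
   on $\beta_1$ implements the direction constraint — with up to 500
   iterations, a relative tolerance of about $2\times10^{-7}$
   (`factr = 1e9`), and random-restart logits (default 3 restarts;
   aggressive multistart improves the objective by under 0.03% on cohorts of
   this size, so a single restart is adequate for large ensembles).
   Unconverged fits are excluded from the ensemble and counted.
2. The per-resample weight vectors are averaged (per-block renormalized);
   a `signal_weighted` mode weighting fits by the $|t|$ statistic of their
   index slope is available, but the default is the plain mean.

Generalizability is assessed by **repeated holdout**: 100 random 40/60
splits (training share `floor(0.4 n)`); weights are estimated by a
100-bootstrap ensemble on each training part, the index is frozen and
computed on the holdout part, and the linear index model is fit there by
OLS.  Decile breakpoints are computed once on the full cohort and frozen —
this matches the use of pre-specified quantile designations in the scenario
arithmetic, and keeps train/holdout indices on one scale.  Summaries across
repeats report the mean, the SD across repeats as the "Std. Error",
2.5/97.5 percentiles, the fraction of negative estimates, and per-weight
exceedance of the 1/52 guideline.  Per-repeat seeds derive deterministically
from the master seed so any repeat can be reproduced alone.

## g-computation

The marginal ("what is" vs "what if") effect of a metric $M$ — the
centered-and-scaled WQS index, or the nutrition index — is estimated by the
parametric g-formula: fit $y$ on $\{M, x, Mx, z\}$ by least squares, set
every subject's $M$ to each counterfactual level, predict, average within
boys / girls / overall, and difference the averages (what-if minus what-is).
Percentile confidence intervals come from a subject-level nonparametric
bootstrap (default 200 replicates) that repeats fit and prediction.  For a
model without the $Mx$ interaction the marginal difference equals the $M$
coefficient times the level shift exactly, which the tests assert as an
identity.  The default counterfactuals are one SD of the metric: index at the
mean versus one SD below (on the standardized scale, $0$ vs $-1$), and
nutrition index at its mean versus one SD above (e.g. $66.8 \to 80.8$).
Causal reading rests on the usual identifiability conditions — consistency,
conditional exchangeability given the covariates, and positivity — which are
assumptions about the data, not properties the code can check; the code does
warn when a counterfactual level lies more than one SD outside the observed
metric range (a positivity red flag).  Weights are *frozen* at the ensemble
average when the index is the metric; they are not re-estimated inside the
bootstrap.

## Reduction scenarios

Each subject's index decomposes exactly into the five class contributions
$\sum_{j \in \text{class}} w_{s(i),j} q_{ij}$.  PFAS and persistent
chlorinated compounds form the *persistent* group (not realistically
reducible); phenols, plasticizers and other short-lived compounds are
*non-persistent*.  A scenario is a per-class retention multiplier in $[0,1]$
applied to the contributions; the standard battery evaluates retaining 30% of
the non-persistent classes (a 70% cut) and eliminating plasticizers,
plasticizers + short-lived, and plasticizers + phenols, reporting the share
of subjects whose adjusted index falls strictly below the target
$\bar{W} - \mathrm{SD}(W)$ together with histogram data.  Scenario
arithmetic scales *index contributions*, not concentrations: re-deriving
decile scores from reduced concentrations would change the population
quantiles and break comparability with the fitted weights.  A
concentration-space mode is deliberately out of scope.

## The synthetic cohort generator

Real cohort data of this kind are restricted, so the package ships a
generator whose defaults define the validation conditions:

* **Exposures.** 26 chemicals in five classes (4 phenols, 9 plasticizer
  metabolites, 3 short-lived, 6 PFAS, 4 chlorinated; summed variables appear
  as single components), lognormal marginals coupled by a Gaussian copula
  with block-exchangeable correlation — 0.4 within class, 0.1 between
  (overridable; the generating literature describes "complex" correlation
  without numbers, so these are stated choices, not estimates).  Detection
  rates default to near 100%; values under the detection quantile are
  flagged and later substituted at LOD/√2 (a documented convention — the
  substitution rule used on the original data is not stated).  Creatinine is
  lognormal with mean 10.4, SD 4.7 mmol/L.
* **Covariates** are drawn independently from the published cohort marginals
  (nutrition index 66.8/14.0, energy 1895/545 kcal, age 31.3/4.6 y, weight
  68.8/13.5 kg, Raven IQ 114.8/14.9, 69% college-educated, 11% smokers, 51%
  girls).  An optional `confound` coefficient tilts the nutrition index
  against log-exposure burden for g-computation stress tests.
* **Outcome** from the stratified interaction model with Table-2-scale
  coefficients ($\beta_0 = 88.7$, $\beta_1 = -2.13$, $\beta_2 = -0.622$,
  $\beta_{12} = 1.98$, covariate effects led by maternal IQ, education and
  nutrition) and residual SD 10 IQ points.  The default true weights are
  sparse — 8 active boy chemicals at $0.5/8$ and 6 active girl chemicals at
  $0.5/6$, spanning all five classes — giving recovery tests a known
  support; equal block masses keep the truth inside the estimator's
  identified set.

What the generator does *not* emulate: exposure–covariate confounding (off
by default), non-lognormal tails, batch effects or measurement error in the
assays, attrition, and any dependence of detection limits on batches.
Passing tests on this cohort show the *procedure* is correct and calibrated
under the stated model; they do not certify performance on real data with
different correlation geometry or confounding.

## What the validation studies show — and an honest limitation

With the default truth, the mixture explains roughly 2% of outcome variance
in boys (slope −2.13 × index SD ≈ 1.5 IQ points against σ = 10) and
essentially nothing in girls (slope −0.15).  Three empirical facts from the
package's own validation (50 cohorts of n = 678, 20 repeats × 50 bootstraps;
the scaled-down study sizes are stated in `tests/testthat/test-acceptance.R`):

* The repeated-holdout mean of the boys' slope is attenuated by roughly 20%
  (≈ −1.6 versus −2.13), with an across-cohort SD of ≈ 0.8.  This is
  errors-in-index attenuation from estimating 52 weights at this
  signal-to-noise, not an optimization failure: multistart searches improve
  the objective negligibly and do not move the slope.
* All eight active boy-stratum chemicals exceed the 1/52 guideline on
  average; inactive chemicals stay near or below it.
* Girl-stratum weights are statistically unidentifiable at slope −0.15: their
  ensemble means hover at the uniform 1/52 regardless of activity status.
  Flagging girls' chemicals of concern under these conditions is beyond any
  estimator's reach at this sample size — a caveat that applies equally to
  weight profiles estimated from real cohorts when a stratum's slope is near
  zero.

Bootstrap percentile intervals for the g-computation marginal difference
cover the analytic truth at close to the nominal 95% (measured within
91–98% across 200 cohorts).

## Numerical choices and degenerate inputs

* Decile breakpoints are type-7 empirical quantiles; ties at a breakpoint go
  to the upper bin, making scores invariant under strictly monotone
  transforms.  Heavy ties that collapse breakpoints emit a warning and the
  scores simply skip bins (still 0..K−1).
* The simplex is parameterized by logits bounded at ±20 (weight ratios up to
  e^40, effectively unrestricted while preventing overflow).
* Bootstrap resamples and random splits that lose a sex stratum are redrawn
  (up to 10 times), then rejected.
* Zero-variance metrics, empty mixtures after filtering, rank-deficient
  designs (with the collinear column named) and sex codes outside {0, 1} are
  rejected with informative errors.
* `run_pipeline()` derives all stage seeds from one master seed; a re-run
  with the same configuration reproduces the report bundle byte-identically
  (the manifest deliberately carries no timestamp).

## Open choices resolved here

* The interaction slope $\beta_1 + \beta_{12}$ is left unconstrained in
  sign; only the reference slope is constrained.  The shrunken girls' slope
  the method reports would be distorted by a hard constraint on the sum.
* Ensemble averaging defaults to the plain mean; significance weighting is
  exposed as an option (`signal_weighted`) but not the default.
* Quantile breakpoints are estimated once on the full sample rather than
  within each training split (see the repeated-holdout section).
* The bootstrap count for g-computation defaults to 200.
* The package's interface is its R functions and `run_pipeline()`; no shell
  entry point is shipped, since analyses of this kind are driven from R.
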