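---
title: "Twin models for continuous traits, extremes, and diagnoses"
author: "biometwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin models for continuous traits, extremes, and diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biometwin)
```

## The scientific question

Many psychiatric conditions appear to be the extreme end of continuously
distributed traits rather than categorically distinct entities.  The twin
design can test this *etiologically*: if the genetic influences on a
diagnosis are largely the same ones that push scores up and down in the
general population, the diagnosis behaves like the tail of a continuum.
`biometwin` implements the full analysis chain this question needs for one
continuous phenotype (here, a disordered-eating questionnaire total on a
1–6 scale) and binary diagnoses ascertained from registries and reports:

1. univariate ACE-family variance decomposition of the continuous score;
2. DeFries–Fulker (DF) extremes analysis at percentile-defined severity
   cut-offs;
3. liability-threshold models for dichotomized or diagnosed outcomes;
4. joint categorical–continuous bivariate models yielding genetic
   (`rA`) and non-shared environmental (`rE`) cross-trait correlations,
   the phenotypic correlation `rPH`, and the *bivariate heritability* —
   the share of `rPH` attributable to shared genetic factors.

## The model

The classical twin design contrasts monozygotic (MZ) pairs, who share all
segregating alleles, with dizygotic (DZ) pairs, who share half on
average.  A phenotype is decomposed as `y = aA + cC + eE` with
independent standard-normal factors: additive genetic `A` (correlated 1
in MZ, 0.5 in DZ), shared environment `C` (correlated 1 within any pair),
and non-shared environment `E` (uncorrelated; absorbs measurement error).
Standardized, the expected twin correlations are

    rMZ = a² + c²,   rDZ = ½ a² + c²

and for an ADE variant (non-additive genetic `D` instead of `C`):
`rMZ = a² + d²`, `rDZ = ½ a² + ¼ d²`.  All models are fitted by full
maximum likelihood on pair-level data with means and variances equated
across twin order and zygosity — an assumption that `assumption_tests()`
checks by likelihood ratio against the unconstrained saturated model.

For binary traits, a standard-normal liability with the same ACE
structure exceeds a threshold `t`; the per-zygosity 2×2 tables are
multinomial with cell probabilities given by bivariate-normal orthant
integrals Φ₂(t, t; r).  The joint categorical–continuous model couples a
continuous trait and a liability trait through cross-trait factor
correlations (`rA`, `rC`, `rE`) in a correlated-factors parameterization;
per pair, the likelihood factorizes as the bivariate-normal density of
the two scores times the conditional orthant probability of the two
binary outcomes given the scores (the 4-variate integral reduces to a
2-D one by conditioning).  The identities

    rPH = rA·a₁·a₂ + rC·c₁·c₂ + rE·e₁·e₂
    bivariate h² = rA·a₁·a₂ / rPH

are computed from the estimates and hold exactly by construction.

## Numerical choices

**Bivariate-normal CDF.**  Orthant probabilities use Gauss–Legendre
quadrature (6/12/20 nodes by |ρ|) on the arcsin(ρ) integral identity for
|ρ| < 0.925, vectorized over thresholds, and adaptive 1-D quadrature of
the conditional-normal representation near |ρ| = 1.  Absolute error is
below 1e−10 (the test suite checks 1e−8 against an independent nested
quadrature written in the tests).  Nothing is Monte Carlo, so every fit
is bit-reproducible.

**Parameterization.**  Standardized variance proportions are squared-path
ratios of unconstrained reals, e.g. `a² = p_a²/(p_a² + p_c² + 1)` with
the E path fixed at 1.  This keeps every component non-negative, sums
them to one exactly, and keeps `e² > 0` structurally.  A consequence
worth knowing: dropping a component places it on the boundary of the
parameter space, so the plain χ² reference for the likelihood-ratio test
is conservative.  The plain χ² is nevertheless the default (the common
convention in this literature); `lrt(..., boundary_mix = TRUE)` applies
the 50:50 mixture reference instead.

**Optimization.**  Quasi-Newton (BFGS) polishing after Nelder–Mead from
several documented starting points: moment-based estimates (twin
correlations mapped to components), an equal-split `(1/3, 1/3, 1/3)`, and
a perturbed split.  Non-finite likelihoods (e.g. non-positive-definite
implied covariance in the joint model) are penalized, never silently
clipped.

**Profile-likelihood confidence intervals.**  Intervals for standardized
components and cross-trait correlations re-optimize all nuisance
parameters at fixed values of the target, and locate the points where the
deviance rises by `qchisq(0.95, 1) = 3.84`.  This respects the [0, 1] and
[−1, 1] boundaries (an interval endpoint at the boundary is reported as
such).  The joint model's profile loop warm-starts each nuisance
re-optimization from the solution at the nearest previously profiled
value, which keeps the search on the continuous profile path.

**Information criteria.**  `AIC = −2LL + 2k`; `BIC = −2LL + k·log(N)`
with `N` the number of *pairs* by default — the sampling unit of the
likelihood.  Using individuals instead is defensible and available via
`bic_n = "individuals"`; the choice only shifts all BICs by a constant
within a comparison of models fitted to the same data, so best-model
designation is unaffected.

## DeFries–Fulker extremes analysis

Probands are individuals in the most severe `p`% of the pooled score
distribution — severity is the *high* end of the scale here, so "1st
percentile" means the top 1% of scores; selection is on ranks, making it
invariant to the log transform.  Scores are transformed affinely so the
population mean is 0 and the proband mean is 1; the transformed co-twin
means then read like twin correlations.  Group heritability `h²g` is
estimated two ways, which the test suite requires to agree within 0.03 at
study size:

* **regression** — the classical double-entered regression
  `C = B₁P + B₂R + A` with `R` the coefficient of relationship (1 MZ,
  0.5 DZ); after the transformation `h²g = B₂`.  Concordant proband
  pairs enter twice (once per proband), so standard errors are
  cluster-robust on pair id (`sandwich::vcovCL`).
* **model fitting** — the ML analogue: co-twin scores are normal with
  mean `b₁P + h²g·R + c²g` and a free variance per zygosity, with a
  profile-likelihood CI on `h²g`.  Double-entered rows are treated as
  independent in this likelihood, so its CI is mildly anticonservative
  relative to the cluster-robust one; both are labeled in the output.

`h²g` is clipped to [0, 1] for reporting; the raw value is kept in
`diagnostics`.  Selecting the whole sample as probands makes the
transformation degenerate (proband mean = population mean) and is
rejected; a wide-but-proper tail (e.g. `p = 50`) approaches the
full-sample individual-differences estimate, which the tests verify.

## The synthetic cohort generator

Registry-linked twin cohorts cannot be redistributed, so the package
ships a generator whose defaults emulate the study design the analyses
are meant for: 1481 female same-sex pairs (768 MZ, 713 DZ); a continuous
score with AE structure and heritability 0.65, reported on a bounded 1–6
scale with mean 2.66, s.d. 0.90, skew 0.57; an anorexia-nervosa-like
diagnosis (prevalence 2.4%, liability h² 0.63, rA 0.26, rE 0.60 with the
score) and an other-eating-disorder-like diagnosis (prevalence 3.3%,
h² 0.67, rA = rE = 0.52).  Latent factors are drawn explicitly (A shared
structurally in MZ pairs, split `√.5` shared + `√.5` unique in DZ pairs),
which makes the MZ/DZ correlation structure true by construction rather
than by a covariance-matrix assumption, and extends directly to two
correlated traits.

**Skew transform.**  The bounded skewed scale is produced by a strictly
monotone map of the standard-normal phenotype: a shifted-lognormal curve
`α + β·exp(δz)` whose tails ease exponentially (C¹) into the open
interval (1, 6) instead of clipping hard — hard clipping would create
ties and break rank preservation.  The three parameters are calibrated
once per target by Gauss–Hermite quadrature so the *transformed* variable
hits the target mean/s.d./skew; targets with |skew| < 0.02 use the exact
affine limit of the family.  The natural log then shrinks the skew
magnitude (it overshoots zero slightly in this family — the transformed
scale is not exactly shifted-lognormal because of the easing), matching
how such scores are handled in practice: analyses run on the
z-standardized log score.

**What the generator does not emulate:** item-level response structure
(totals only), sex-limitation and age effects, ascertainment biases in
registry linkage, and any AN–OED dependence beyond what their shared
correlation with the score induces (the two diagnoses are conditionally
independent given the score's factors).  Passing tests therefore
establish that the estimators recover known ground truth under the
stated model, not that the model is true of any real cohort.

**Seeds.**  One master seed per configuration; every generator call is a
pure function of (config, seed).  The multi-trait cohort generator calls
the bivariate generator twice with the same seed, so the score columns
are identical regardless of which diagnosis accompanies them.

## Degenerate inputs and edge policies

* A zygosity group with affected twins but no concordant pair can drive
  the tetrachoric correlation to −1.  The atanh parameterization
  flattens near the boundary, so the edge deviance is evaluated exactly
  at ρ = ±1 and the estimate snaps to the boundary (flagged
  `boundary = TRUE`) when the edge fits as well — reported, never
  silently returned.
* A group with no affected individuals at all is `inestimable`.
* The liability-threshold fit at the 1st percentile of a study-size
  cohort involves ~15 concordant-or-discordant pairs and is not run by
  default (`liability_min_percentile = 3` in `run_study()`).
* Joint-model parameter sets whose implied 4×4 covariance is not
  positive definite receive a penalty likelihood, keeping the optimizer
  inside the feasible region.

## Design decisions that were genuinely open

* **Missing ascertainment flags are treated as absent** when classifying
  cases (parent reports are typically available for only part of a
  cohort); per-source availability is reported separately so the
  missingness is visible rather than hidden in the prevalence.
* **Individuals flagged for both AN and other-ED sources are classified
  AN** (AN precedence), matching clinical convention for registry-based
  ED grouping.
* **Single missing items** within a subscale that still meets its ≥75%
  completion minimum contribute nothing to the total: the score is the
  mean of answered items.
* **The liability threshold in joint models is estimated freely**
  (equated across twins and zygosity) rather than fixed to a register
  prevalence; with complete pair data the two choices coincide
  asymptotically, and free estimation keeps the deviance comparable
  across nested models.
* **D (non-additive genetic) terms are off by default** everywhere: the
  cohorts this package emulates select AE models, and a joint ADE model
  is deliberately out of scope.  When ADE is requested in the univariate
  module, DZ non-additive sharing is fixed at the standard 0.25.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on generated data:
moment-convergence checks use 50 000–300 000 pairs per zygosity where
closed-form expectations are compared at tight tolerance; estimator
calibration (bias, CI coverage, method agreement, severity-trend) uses
100 replicate cohorts at the study size of 768 MZ + 713 DZ pairs; joint
models are exercised at study size for point estimates and on smaller
cohorts (250–700 pairs per zygosity) where profile CIs are stressed.
The acceptance script averages each stochastic stage over 10 replicate
study-size cohorts so that reported values reflect the estimator rather
than a single draw.

## Known limitations

* Pearson correlations of the *transformed* (bounded, skewed) scale are
  mildly attenuated relative to the latent normal scale — visible as
  sample rMZ slightly below `a² + c²` on the raw scale.  The analysis
  pipeline works on the z of the log score, as the emulated study did,
  and inherits the same small distortion.
* Profile CIs from double-entered DF likelihoods understate uncertainty
  slightly (rows are not independent); use the cluster-robust regression
  interval when the CI itself is of interest.
* The LRT for dropping a variance component uses the conservative plain
  χ² by default (see above).
* `fit_joint` with the full ACE family and profile CIs is the most
  expensive operation (~1 minute per fit at study size on one core);
  `ci = "none"` fits in a few seconds.
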