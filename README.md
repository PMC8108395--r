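# biometwin

Biometrical twin modeling of a continuous phenotype and binary
diagnoses: does a disorder look like the extreme end of a continuously
distributed trait, or like a distinct entity?

`biometwin` is built for the classical female same-sex twin-cohort
setting in psychiatric epidemiology — a questionnaire measure of
disordered eating on a 1–6 scale, plus eating-disorder diagnoses
ascertained from a patient register, parent-reported treatment, and
self-reported purging — but every estimator is generic over pair-level
twin data.

## What it computes

Writing the phenotype of one twin as `y = aA + cC + eE` (additive
genetic, shared environment, non-shared environment; standardized
components `a² + c² + e² = 1`), the expected twin correlations are
`rMZ = a² + c²` and `rDZ = ½a² + c²`. On top of this the package
provides:

* **Univariate ACE family** (`fit_ace`, models ACE/ADE/AE/CE/E) by full
  maximum likelihood, with saturated-model assumption tests
  (`assumption_tests`), ML twin correlations (`twin_correlations`), and
  profile-likelihood 95% CIs on the standardized components.
* **DeFries–Fulker extremes analysis** (`group_heritability`,
  `extremes_table`): probands defined by percentile cut-offs of the
  score, scores transformed so population mean = 0 and proband mean = 1,
  and group heritability `h²g` estimated both by the classical
  double-entered regression `C = B₁P + B₂R + A` (with cluster-robust
  standard errors) and by its maximum-likelihood model-fitting analogue.
* **Liability-threshold models** (`fit_liability`,
  `tetrachoric_correlations`, `probandwise_concordance`): binary
  outcomes as a thresholded standard-normal liability, per-zygosity 2×2
  tables with bivariate-normal orthant probabilities computed by
  deterministic quadrature (`pbvn_upper`, abs. error < 1e−10).
* **Joint categorical–continuous bivariate models** (`fit_joint`,
  `cross_twin_cross_trait`): one continuous and one liability trait with
  cross-trait factor correlations, yielding `rA`, `rE`, the phenotypic
  correlation `rPH = rA·a₁·a₂ + rC·c₁·c₂ + rE·e₁·e₂`, and the bivariate
  heritability `rA·a₁·a₂ / rPH` — the share of the trait–diagnosis
  correlation explained by shared genes.
* **Model comparison** (`lrt`, `compare_models`, `select_best`):
  likelihood-ratio tests against saturated/parent models, AIC/BIC, and
  best-model designation favoring the most reduced adequate model.
* **Phenotype construction** (`score_edi2`, `classify_ed`,
  `cohort_summary`): 23-item questionnaire scoring with per-subscale
  75%-completion rules, ICD-10 code handling, three-source case
  classification with AN precedence, and prevalence/overlap reporting.
* **Synthetic cohorts** (`sim_config`, `simulate_continuous`,
  `simulate_binary`, `simulate_bivariate`, `simulate_study_cohort`):
  latent-factor twin simulation with known ground truth, including a
  calibrated monotone transform onto a bounded right-skewed 1–6 scale.
* **Pipeline** (`run_study`): the full workflow — descriptives,
  assumption tests, ACE family, extremes, liability, joint models — as
  one reproducible call with JSON/CSV report output.

## Worked example

```r
library(biometwin)

# a study-sized synthetic cohort: 768 MZ + 713 DZ pairs, disordered-eating
# score on the 1-6 scale plus AN-like and OED-like diagnoses
pairs <- simulate_study_cohort(seed = 42)

# analysis scale: z of the log score
z <- log(c(pairs$t1_score, pairs$t2_score)); z <- (z - mean(z)) / sd(z)
n <- nrow(pairs)
ana <- pairs
ana$t1_score <- z[1:n]; ana$t2_score <- z[n + 1:n]

twin_correlations(ana)
#>   zygosity         r    lower     upper
#> 1       MZ 0.6455226 0.605781 0.6811980
#> 2       DZ 0.2987694 0.230739 0.3627871

fit_ace(ana, "AE")
#> AE model fit (768 MZ + 713 DZ pairs)
#>   -2LL = 7920.598  npar = 3  AIC = 7926.598  BIC = 7942.500
#>   a2 = 0.643  (95% CI 0.603-0.679)
#>   e2 = 0.357  (95% CI 0.321-0.397)

group_heritability(ana, 5)
#> DF extremes analysis at the 5th percentile: 149 probands
#>   transformed co-twin means: MZ 0.667, DZ 0.234
#>   h2g (regression) = 0.860 (95% CI 0.563-1.000)
#>   h2g (model) = 0.858 (95% CI 0.586-1.000)

fit_joint(ana, "AE", dx_cols = c("t1_oed", "t2_oed"), ci = "none")
#> Joint categorical-continuous AE model (768 MZ + 713 DZ pairs)
#>   -2LL = 8622.851  npar = 7  AIC = 8636.851  BIC = 8673.954
#>   continuous trait: a2 = 0.643, c2 = 0.000, e2 = 0.357
#>   liability trait:  a2 = 0.759, c2 = 0.000, e2 = 0.241 (threshold 1.772)
#>   rA = 0.575  rE = 0.676
#>   rPH = 0.600  bivariate heritability = 0.669
```

Reading the output: the MZ twin correlation (0.65) is about twice the DZ
correlation (0.30), the signature of additive genetic influence; the AE
model estimates 64% of score variance as genetic. The DF co-twin means
behave like twin correlations in the extreme tail, and `h²g` says the
genes behind extreme-group membership also drive continuous variation
(this single 149-proband draw lands high — the CI is wide at the 5th
percentile). In the joint model, `rA = 0.58` with bivariate heritability
0.67 means roughly two-thirds of the score–diagnosis correlation is
genetic in this cohort draw.

The whole workflow in one call:

```r
report <- run_study(pairs, binary_traits = c("an", "oed"),
                    percentiles = c(1, 3, 5, 10), outdir = "report")
```

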