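---
title: "Composite senescence scoring and the association grid: models, conventions, and limits"
author: "senescore maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite senescence scoring methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senescore)
```

# The scientific problem

Cellular senescence — a largely irreversible growth arrest of cells that
remain metabolically active — leaves a transcriptional footprint in bulk
blood RNA-seq. It can be summarized by composite gene-expression scores over
curated gene lists: the canonical senescence pathway (CSP, 22 genes, cell
cycle arrest), the senescence-initiating pathway (SIP, 48 genes,
macromolecular damage), the senescence response pathway (SRP, 44 genes,
SASP — the pro-inflammatory secretome), their deduplicated 112-gene summary
union, and the 125-gene SenMayo SASP list. `senescore` implements this
scoring pipeline end to end together with the population-level analysis it
feeds: survey-weighted regressions linking the scores to socio-behavioral
factors and to aging outcomes (epigenetic pace of aging, clock-based age
acceleration, biological-age acceleration, multimorbidity, cognition, and
6-year mortality), with batch adjustment, Benjamini-Hochberg FDR, and k-fold
cross-validation.

The population data such analyses are run on are restricted-access, so the
package ships a first-class synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, plus a truth record that makes
parameter-recovery testing possible.

# Scoring model

For sample $i$ and a gene set of size $G$,

$$\mathrm{Score}_i = \frac{1}{G} \sum_{g=1}^{G}
  \frac{\mathrm{log_2CPM}(g)_i - \overline{\mathrm{log_2CPM}(g)}}
       {\mathrm{sd}\!\left(\mathrm{log_2CPM}(g)\right)}.$$

Conventions, each of which matters for bit-level reproducibility:

* **RLE scale factors.** Each gene's reference is the geometric mean of its
  counts across samples; any zero count forces a zero reference, so such
  genes never contribute a ratio. A sample's raw factor is the median across
  usable genes of count/reference (even-length medians are the mean of the
  two central order statistics), and raw factors are rescaled to geometric
  mean 1. At least one gene must be positive in every sample, otherwise
  normalization aborts and asks for filtering.
* **Effective library size.** `log2Cpm()` uses raw library size times the
  factor. This composition is stated here as the package's single normative
  formula: a gene-wise doubled sample gets factors
  $(2^{-1/2}, 2^{1/2})$, and the per-sample prior is scaled with the
  effective library size, $p_j = \text{priorCount} \cdot L_j/\bar L$
  (default priorCount 2), giving
  $\log_2\big((c_{gj}+p_j)/(L_j+2p_j)\times 10^6\big)$. Zero counts map to
  finite values for any positive prior, and values are strictly increasing
  in the count within a sample.
* **Z-scoring.** Per gene across the scored sample, with the $n-1$
  (sample-SD) denominator; zero-variance genes are excluded with a logged
  reason rather than divided by zero. Standardization is computed on
  whatever sample is scored, unweighted — survey weights enter only at the
  association stage.
* **Summary score.** The mean over the deduplicated 112-gene union of
  CSP/SIP/SRP (the sentinel genes IGFBP7 and AKT1 sit in both SIP and SRP
  and are used once), *not* the mean of the three sub-scores; a
  definitional test pins this down on a toy matrix.
* **Missing members.** The default `missingPolicy = "error"` refuses to
  silently change a score's meaning; `"drop"` is opt-in and records the
  number of genes actually averaged.
* **Identifier matching** is exact string match after whitespace stripping;
  no alias resolution.

Every score column therefore has sample mean zero by construction, which is
asserted to $10^{-8}$ in the tests.

# The synthetic cohort

`cohortConfig()` holds the generator's population parameters; the defaults
are the package's study conditions and are not tuned per analysis:

* 3580 samples; a 1000-gene universe carrying the default gene-set geometry
  (22/48/44/125 with SIP∩SRP = 2 and SenMayo overlapping CSP/SIP/SRP by
  1/4/22, no triple intersections). The universe size is a deliberate
  scale-down of a whole transcriptome that keeps the senescence genes a
  minority (~21% of genes), which the RLE majority-unchanged assumption
  needs; with near-saturated universes the library-size correction itself
  absorbs the senescence signal.
* Negative-binomial counts, mean–dispersion parameterization
  ($\mathrm{Var} = \mu + \mu^2/\theta$, default $\theta = 10$), gene
  baselines log-uniform over expected counts 5–500, log-normal library
  offsets (SD 0.2), 46 batch plates with additive gene-independent
  log-scale shifts (SD 0.1).
* A standardized latent senescence factor built as a linear combination of
  covariates (defaults: age group 0.12, female 0.05, BMI class 0.06, weekly
  drinks 0.03, all standardized) plus Gaussian noise scaled to unit
  variance; senescence-set genes load on it uniformly in [0.15, 0.35] on
  the log scale.
* Outcomes linked to the factor at programmed standardized effects
  (pace-of-aging mean 1/SD 0.1; clock age acceleration SD 4 y; biological
  age = chronological age + an 8.1-y-SD acceleration; cognition on a latent
  normal rescaled to mean 15.5/SD 4.3 then rounded and clipped to 0–27;
  multimorbidity Binomial(5, p) with a logit link around baseline p = 0.16).
  Six-year mortality comes from a logistic model whose intercept is solved
  numerically so the marginal rate equals the configured 0.162; vital
  status is 4-category (1 contacted alive, 2 presumed alive — 10% of
  survivors by default, 3/4 known deceased split evenly), with a small
  missing-status fraction (26/3580). Mortality is coded deceased iff status
  is 3 or 4.
* Gamma survey weights (shape 4, mean 1), tilted by age group by default so
  that weighting is consequential in tests rather than decorative; immune
  cell-type proportions from a gamma (logistic-normal-like) construction
  mildly tilted by the latent factor.

What the generator does **not** emulate: the sampling design, nonresponse
and weight construction of a real panel survey; realistic gene–gene
correlation beyond the single latent factor; age-varying sex ratios;
measurement error in self-reports. Passing tests therefore show that the
pipeline's statistics behave correctly under the assumed data-generating
model, not that the published population estimates are reproduced — those
live on restricted data.

# Association conventions

* **Standardized coefficients.** Continuous predictors and (for linear
  models) the outcome are z-scored on each model's complete-case analysis
  sample; 0/1 indicators and factor dummies stay binary. The reported
  linear coefficients are thus fully standardized betas, and logistic
  models report the odds ratio per SD of the focal predictor. This is the
  most common convention for "standardized coefficients" and is applied
  uniformly.
* **Weights and variance.** Analytic (survey) weights enter the least
  squares / likelihood directly; with weights present,
  heteroskedasticity-robust sandwich standard errors are used (HC1 for
  linear, HC0 for logistic), approximating design-based survey variance
  without stratum/cluster information. Frequency-weight equivalence of
  point estimates is exact and tested.
* **Filters.** Complete cases per model; mortality models can exclude
  "presumed alive" (status 2) rows as a sensitivity filter;
  biological-age acceleration is the OLS residual of biological on
  chronological age over the non-missing rows, computed before
  model-specific filtering.
* **FDR families.** Benjamini-Hochberg within the score-prediction family
  across the models that differ in their dependent variable (the five
  scores), term by term; and within each outcome across the five score
  models for the outcome families. `bhFdr()` validates inputs and delegates
  to the canonical step-up implementation; a brute-force evaluation of the
  step-up definition serves as the independent oracle in the tests.
* **Cross-validation.** Seeded fold assignment; logistic folds are
  stratified by a stable per-class shuffle followed by round-robin
  assignment (a class smaller than k aborts). Out-of-sample
  $R^2 = 1 - SSE/SST$ with SST from the held-out fold; logistic RMSE/MAE
  are computed on predicted probabilities against the 0/1 outcome — a
  documented convention, since no standard exists for that case. The
  full-sample $R^2$ uses the same convention on the whole sample.

# Numerical choices and degenerate inputs

Medians of even-length ratio vectors are the mean of the two central order
statistics. Seeds are consumed deterministically; `generateCohort()`
derives a child seed for the count draws so phenotype and count streams do
not interleave. Collinear designs abort naming the aliased columns;
logistic separation and non-convergence abort with diagnostics; zero
effective library sizes, nonpositive priors, out-of-range p-values,
infeasible overlap geometries, and unknown effect keys are all rejected
with named errors rather than silently repaired.

# Validation problem sizes

The checks this package runs on itself use deliberately modest sizes chosen
to exercise the asymptotics that matter while keeping the suite quick:
score-mean and oracle checks on a 500-gene × 1000-sample cohort; RLE
factors against a brute-force median-ratio oracle on 100 random small
matrices at $10^{-12}$; BH-FDR against the step-up definition on 1000
random p-vectors; parameter recovery at n = 3000 over 50 seeds (programmed
standardized effect 0.24 recovered within ±0.05; programmed OR-per-SD 1.5
with geometric-mean estimate inside [1.4, 1.6]); type-I calibration over
200 null model fits (empirical rate within [0.03, 0.07] at α = 0.05); and
the directional CV property (mean 5-fold CV $R^2$ not exceeding the
full-sample $R^2$) over 50 seeds.

# Known limitations and open choices

* The effective-library-size composition above over-corrects relative to
  the convention in which the median ratio alone plays the role of relative
  depth; the tests cross-check the raw median ratios against the
  established RLE implementation after converting conventions, and the
  composition is documented here so downstream users can reason about it.
* Whether weighted analyses should use full design-based variance
  estimation is left open by the available information; robust sandwich
  errors are the documented approximation.
* Descriptive summaries of generated cohorts are unweighted by default;
  weights are recorded per sample and used in all model fits.
* Z-scoring uses the scored input sample as the standardization population.
* No gene filtering precedes normalization by default (a configuration hook
  exists via upstream filtering of the count matrix); no TMM or
  upper-quartile alternatives; no survival modeling (mortality is a binary
  6-year outcome); no causal or mediation decomposition.
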