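---
title: "Multi-cohort prognostic meta-analysis with metasig"
author: "metasig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-cohort prognostic meta-analysis with metasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

## Overview

`metasig` estimates the prognostic value of genes and gene signatures across
many independent expression cohorts at once. Its pipeline is: standardize
each cohort (probe-to-gene collapsing, duplicate-sample removal, sample-type
and cohort-size filters); estimate a per-cohort hazard for every gene with
the D-index; pool per-cohort estimates with a random-effects model; select a
cross-cancer signature by FDR and hazard-ratio thresholds; score patients by
a signed average; and validate the signature on held-out cohorts, overall
and within molecular subtypes, against a random-signature permutation null.

This vignette documents the statistical model, the choices behind each
tunable parameter, what the synthetic-cohort generator does and does not
emulate, and the package's numerical conventions and limitations.

## The D-index

A Cox model fitted directly to an expression value is sensitive to the
measurement scale, which differs across platforms. The D-index removes the
scale: risk scores are ranked (average ranks over ties), mapped to expected
normal order statistics via Blom's approximation
$z_i = \Phi^{-1}\!\big((r_i - 3/8)/(n + 1/4)\big)$, divided by
$\kappa = \sqrt{8/\pi}$, and a univariate Cox model with Efron tie handling
is fitted to $z$. The coefficient $D$ estimates the log hazard ratio
comparing the upper and lower halves of the prognostic distribution; any
strictly increasing transform of the scores yields the identical estimate.

Two consequences matter when interpreting results:

* For a normally distributed prognostic index with per-SD Cox coefficient
  $\beta$, the large-sample D-index is $\kappa\beta$ ($\kappa \approx
  1.596$). A gene whose expression carries a marginal log HR of 0.35 per SD
  therefore shows a pooled D-index HR near $e^{0.56} \approx 1.75$, not
  $e^{0.35}$. The tests use this mapping as their theoretical oracle, e.g.
  a design with $\beta = \ln 2 / \kappa$ must yield an HR near 2.
* When several independent risk factors contribute to the hazard, the
  *marginal* association of any one of them is attenuated by the residual
  risk heterogeneity (a frailty effect inherent to proportional-hazards
  models, of order 10–25% under the generator's defaults). Calibration
  windows in the tests account for it.

The Cox solver is a single-covariate Newton–Raphson with step-halving,
convergence when the coefficient moves by less than `1e-9`, and at most 50
iterations; non-convergence, constant covariates and fewer than two events
are reported as degenerate inputs, which genome-wide scans skip gene-wise
(decrementing the number of contributing cohorts). Efron's tie correction is
used because day-resolution survival data contain ties and Efron is the
accepted default. The covariate is centred before exponentiation to avoid
overflow. The risk-set bookkeeping depends only on the endpoints, so a scan
prepares it once per cohort and reuses it for every gene.

## Random-effects pooling

Per-cohort estimates $(\hat\theta_i, s_i)$ are pooled by inverse-variance
weighting. The between-study variance uses the DerSimonian–Laird moment
estimator
$\tau^2 = \max\!\big(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\big)$
with $Q$ Cochran's statistic on the fixed-effects weights $w_i = 1/s_i^2$.
The pooled p-value is a two-sided normal test of the pooled z-score —
estimates are pooled, not per-cohort p-values. DerSimonian–Laird is the
classical default for this analysis family; a REML alternative was
considered and rejected as default to keep results reproducible against the
moment estimator's closed form (the test suite checks it against an
independent implementation to 1e-12 and against `metafor`).

## Genome-wide scans and signature discovery

A gene enters a scan when it is estimable in at least `min_datasets`
cohorts. The default of 6 mirrors a compendium in which 12 cohorts carry
overall survival: requiring half guards against genes measured on only one
or two platforms. Benjamini–Hochberg q-values are computed within each
cancer type's scan; cross-cancer selection then intersects the per-type
calls. An alternative joint-BH mode across types exists behind
`gene_universe`/caller-side pooling but is not the default, since per-type
control is the interpretation consistent with reporting per-cancer tables.

Selection requires, in **every** cancer type: q < `fdr_max` (0.05) and
pooled HR > `hr_upper` (1.125) or < `hr_lower` (0.875). The HR band
excludes genes that are statistically significant but prognostically
negligible. Direction concordance across types is required by default: a
gene protective in one cancer and deleterious in another is not a
cross-cancer marker in the signed-average sense. Both thresholds and the
concordance rule are configurable in `selection_config()`.

## Scoring and validation

Signature scores are signed averages: within each cohort, each signature
gene is z-scored across samples, multiplied by its ±1 direction, and
averaged over the genes actually measured (the denominator adapts, keeping
scores comparable across platforms; coverage below 50% triggers a warning).
Within-cohort standardization is essential — raw log intensities are not
comparable across platforms — and mirrors the median-split logic used for
Kaplan–Meier display. A rank-based scaling to [−1, 1] is available via
`method = "rank"` for heavy-tailed platforms.

Validation pools per-cohort D-indices of the scores and concatenates
per-cohort median splits into a single log-rank test. Median splits are
always computed within a cohort (never on pooled scores), so platform
location shifts cannot leak into group assignment. Subtype-stratified
records reuse the full-cohort standardization, then subset samples; a
stratum equal to the whole cohort therefore reproduces the overall record
exactly. Module correlations are Spearman per cohort, Fisher-z transformed
with se $1/\sqrt{n-3}$, pooled by the same random-effects machinery and
back-transformed; |rho| is clipped at 0.9999 to keep the transform finite.

The random-signature null draws `n_random` gene sets of the tested
signature's size uniformly from genes measured in every evaluation cohort,
assigns each gene the direction of its training pooled log-HR sign
("signatures trained identically, but on random genes" — the strictest
version of the random-signature critique; coin-flip directions are
available), and reports the add-one permutation p-value
$(1 + \#\{|D_{null}| \ge |D_{obs}|\})/(n_{random}+1)$ on the absolute
pooled D. With 1000 draws the smallest attainable p is $1/1001 \approx
0.001$.

## The synthetic-cohort generator

`generate_collection()` emulates the statistical structure the analysis
assumes, with known ground truth:

* **Expression.** Per cohort, gene-by-sample standard normal variates plus
  per-gene location shifts (N(0,1)) and scale factors (log-normal, sd 0.2)
  emulating platform effects.
* **Planted prognosis.** Prognostic genes form co-expressed *programs*: a
  latent per-sample risk factor $U \sim N(0,1)$ drives the hazard and member
  genes read it out with loading $\sqrt{0.8}$ (signs alternate by gene). The
  program coefficient is scaled so each member gene's marginal single-gene
  log HR per SD equals the configured effect (default 0.35). One program is
  shared by all cancer types; each type carries one type-specific program.
  Planting many *independent* additive effects instead would create an
  omitted-covariate frailty that attenuates every marginal estimate to a
  fraction of its nominal value, making planted truth unrecoverable by any
  estimator — co-expression is both more realistic and the only
  construction under which "the planted value" is a well-defined marginal
  estimand. Per-dataset effects are jittered with sd `between_study_sd`
  (default 0.05, mild heterogeneity).
* **Survival.** Exponential baseline (default 1/1000 per day, median
  survival near two years untreated by covariates) under proportional
  hazards; administrative uniform censoring with the window calibrated
  numerically (by `uniroot` on the closed-form censoring probability) to a
  target fraction, default 20%.
* **Structure for the curation filters.** Optional multi-probe expansion
  (extra probes are attenuated, noisier copies, so max-IQR collapsing should
  prefer the informative probe), near-duplicate injection across cohorts of
  a type (noise sd 0.03, Spearman rho ≈ 0.999 at genome scale) with an
  exact registry for recall scoring, and subtype labels driven by a
  20-gene block per subtype disjoint from the prognostic genes.
* **Seeding.** One master seed fans out to per-dataset child seeds through
  a counter scheme, so adding cohorts to a configuration never perturbs the
  cohorts already generated.

What the generator does **not** emulate: platform-specific probe chemistry,
normalization artifacts, batch effects within a cohort, non-proportional
hazards, informative censoring, or correlated clinical covariates. Passing
tests on synthetic cohorts therefore demonstrates the pipeline's
correctness under its own assumptions, not robustness to every failure mode
of real compendia.

## Study conditions used by the tests and acceptance script

The default configuration — three cancer types, ten cohorts of 120–180
samples each, 2000 genes, 25 shared planted genes at |log HR| 0.35, ten
type-specific genes per type, 20% censoring — is the condition under which
the package's end-to-end claims are evaluated: training on eight cohorts
per type and holding out two, signature discovery recovers the planted
shared genes with no unplanted selections, the discovered signature
separates holdout survival, and it beats 1000 random signatures at the
smallest attainable permutation p. Null-control runs use the same geometry
with no planted effects (a genome-wide scan then yields a median of zero
genes at q < 0.05 over 20 replicates), and D-index calibration uses a
direct n = 2000 proportional-hazards draw with $\beta = \ln 2/\kappa$.
These sizes keep a full verification run within a few minutes on one CPU
while leaving wide statistical margins; `scripts/acceptance.R` recomputes
all of them from a single `--seed`.

## Numerical conventions and degenerate inputs

* Survival times are days; readers convert months/years at load time.
* Unknown clinical codes become missing (with a warning count), never
  errors: tolerant curation mirrors how heterogeneous public cohorts are
  actually standardized. The vocabulary itself is closed.
* Missing expression stays missing; scoring and correlation drop
  missing values pairwise; a duplicate-candidate pair needs ≥ 30 shared
  non-missing genes to be scored.
* IQR ties in probe collapsing break by annotation order; duplicate
  components keep the member from the largest cohort, then the
  lexicographically first sample id — deterministic choices that make
  curation reproducible.
* Median splits label "high" strictly above the median, so an all-equal
  score vector yields a single group and a warning rather than an
  arbitrary split.
* `d_index` on fewer than two events, constant scores, or a non-converged
  Newton iteration raises a typed degenerate-input condition; scans catch
  it and decrement k.

## Limitations

* Only univariate hazards: no multivariable Cox, time-varying covariates or
  concordance indices.
* The permutation null fixes signature *size*; it does not resample
  patients, so it calibrates gene-set choice, not sampling variability.
* DerSimonian–Laird τ² is known to be noisy at small k; with fewer than
  about five cohorts the random- and fixed-effects results should be read
  together.
* Subtype labels are consumed as given; no subtype classifier is fitted.
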