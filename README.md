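# metasig

Multi-cohort survival meta-analysis and prognostic gene-signature discovery
for transcriptomic data.

## The problem

A gene's prognostic value estimated in one expression cohort rarely
generalizes: platforms, populations and follow-up differ, and signatures
trained on a single dataset often perform no better than random gene sets of
the same size. `metasig` implements the meta-analytic alternative: estimate
each gene's hazard separately in every cohort, pool the estimates with a
random-effects model, select genes that are significant across *several
cancer types at once*, and score patients with a signed average — then hold
the resulting signature to a random-signature permutation null on cohorts it
never saw.

The package is aimed at computational biologists working with collections of
curated expression cohorts (features × samples matrices with standardized
clinical tables) across breast, ovarian and pancreatic cancer or any
comparable multi-cohort setting. A synthetic-cohort generator with planted
prognostic genes makes the whole pipeline testable end to end without any
external download.

## The statistics

- **Per-cohort hazard: the D-index.** For a risk score *x* (a single gene's
  expression or a signature score), samples are ranked, converted to normal
  order statistics by Blom's approximation
  *z* = Φ⁻¹((r − 3/8)/(n + 1/4)), scaled by 1/κ with κ = √(8/π), and a
  univariate Cox model (Efron ties, Newton–Raphson with step-halving) is
  fitted to *z*. The coefficient *D* estimates the log hazard ratio between
  the upper and lower prognostic halves; it depends on the scores only
  through their ranks.
- **Pooling.** Per-cohort estimates are combined by inverse-variance
  weighting with the DerSimonian–Laird between-study variance
  τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)).
- **Genome-wide scans** compute a pooled D per gene (genes present in at
  least `min_datasets` cohorts) with Benjamini–Hochberg q-values.
- **Signature discovery.** A gene enters the signature iff in *every* cancer
  type q < 0.05 and HR > 1.125 or HR < 0.875, with concordant direction;
  direction is +1 iff pooled HR > 1.
- **Scoring.** Signed average: per-gene z-scores within a cohort, multiplied
  by ±1 directions, averaged over the measured signature genes.
- **Validation.** Per-cohort median splits pooled into Kaplan–Meier /
  log-rank tests, subtype-stratified evaluation, and an add-one permutation
  p-value against `n_random` equally sized random signatures whose
  directions are assigned from the training hazards.

The bundled 53-gene multi-cancer signature (41 risk genes, 12 protective)
ships in `inst/extdata/metagx_signature.json`, together with six classic
ovarian prognostic genes and seven breast gene-module prototype genes.

## Worked example

```r
library(metasig)

# three synthetic cancer types, ten cohorts each, 2000 genes,
# 25 shared planted prognostic genes (|log HR| = 0.35 per SD)
sim  <- generate_collection(synthetic_config(seed = 101))
coll <- sim$collection

# hold out the last two cohorts of every type, scan the rest per type
grouping <- attr(coll, "grouping")
holdout_ids <- unlist(lapply(grouping, function(ids) ids[9:10]))
train   <- cohort_collection(coll[setdiff(names(coll), holdout_ids)])
holdout <- cohort_collection(coll[holdout_ids])
scans <- sapply(names(grouping), function(ty)
  genomewide_meta(train, min_datasets = 6, cancer_type = ty),
  simplify = FALSE)

sig <- discover_signature(scans)
print(sig)
#> <gene_signature> discovered: 25 genes (10 risk, 15 protective)

evaluate_signature(holdout, sig, strata = NULL)
#> <signature_evaluation> discovered
#>  stratum k   hr ci_lo ci_hi      d_p logrank_p   n
#>      all 6 1.93  1.61  2.32 1.89e-12  4.33e-17 939
```

All 25 planted genes are recovered with no false selections, and the
signature separates survival on cohorts excluded from training: the pooled
D-index HR between the high- and low-scoring prognostic halves is 1.93
here, with a pooled median-split log-rank p of
4.3e-17 over 939 holdout patients. `random_signature_null()` then shows
the signature beats 1000 random same-size gene sets (p = 1/1001 ≈ 0.001).

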