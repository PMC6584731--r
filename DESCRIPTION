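Package: metasig
Title: Multi-Cohort Survival Meta-Analysis and Prognostic Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for meta-analysis of gene-expression prognosis across many
    transcriptomic cohorts and cancer types. Estimates per-gene hazard via the
    Royston-Sauerbrei D-index (Cox regression on scaled normal order
    statistics), pools per-dataset estimates with a DerSimonian-Laird
    random-effects model, scans genomes with Benjamini-Hochberg FDR control,
    discovers cross-cancer prognostic signatures by FDR and hazard-ratio
    thresholds, scores samples by signed averages of standardized expression,
    and calibrates signatures against a random-signature permutation null.
    Includes curation filters (probe-to-gene collapsing by interquartile
    range, duplicate-sample removal by Spearman correlation, sample-type and
    cohort-size filters) and a synthetic multi-cohort generator with planted
    prognostic genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
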