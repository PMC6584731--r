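# In-code fixture builders for small cohorts with simple survival structure.

# One cohort: iid normal expression, exponential survival driven by a linear
# predictor over (optionally) the first genes, uniform censoring.
make_cohort <- function(dataset_id = "ds1", cancer_type = "synthetic-1",
                        n_genes = 50, n = 60, seed = 1, beta = NULL,
                        subtype = NULL, cens_window = 1500) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  samples <- sprintf("%s_S%03d", dataset_id, seq_len(n))
  x <- matrix(rnorm(n_genes * n), n_genes, n, dimnames = list(genes, samples))
  eta <- if (is.null(beta)) rep(0, n) else drop(crossprod(x[seq_along(beta), , drop = FALSE], beta))
  tm <- rexp(n, 0.002 * exp(eta))
  cm <- runif(n, 0, cens_window)
  time <- pmax(pmin(tm, cm), 0.01)
  event <- as.integer(tm <= cm)
  clinical <- clinical_table(data.frame(
    sample_id = samples, dataset_id = dataset_id, sample_type = "tumor",
    subtype = if (is.null(subtype)) NA else subtype,
    days_to_death = time,
    vital_status = ifelse(event == 1, "deceased", "living"),
    stringsAsFactors = FALSE))
  list(expr = expression_dataset(x, dataset_id = dataset_id,
                                 cancer_type = cancer_type),
       clinical = clinical)
}

make_collection <- function(n_datasets = 3, seed = 1, ...) {
  cohort_collection(lapply(seq_len(n_datasets), function(i)
    make_cohort(dataset_id = sprintf("ds%d", i), seed = seed + i, ...)))
}

# Deterministic small endpoints for hand calculations.
hand_endpoints <- function() {
  list(time = c(5, 8, 12, 16, 20, 24, 30, 33),
       event = c(1, 0, 1, 1, 0, 1, 1, 0),
       group = c(0, 0, 1, 0, 1, 1, 0, 1))
}
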