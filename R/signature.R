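# Cross-cancer signature discovery by FDR and hazard-ratio thresholds,
# signed-average risk scoring, and the random-signature permutation null.

#' Construct a gene signature
#'
#' A gene signature is a set of genes with +/-1 directions: direction +1
#' genes (hazard ratio > 1, risk) are added into the score and direction -1
#' genes (protective) subtracted.
#'
#' @param genes character vector of gene identifiers (unique).
#' @param directions vector of `+1` / `-1`, recycled if length 1.
#' @param name signature name.
#' @param provenance optional data frame of per-cancer evidence per gene.
#' @return object of class `"gene_signature"`.
#' @export
gene_signature <- function(genes, directions = 1, name = "signature",
                           provenance = NULL) {
  if (anyDuplicated(genes)) stop("signature genes must be unique")
  directions <- rep_len(as.integer(directions), length(genes))
  if (!all(directions %in% c(-1L, 1L)))
    stop("directions must be +1 or -1")
  structure(
    list(name = name,
         genes = data.frame(gene = as.character(genes), direction = directions,
                            stringsAsFactors = FALSE),
         provenance = provenance),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d genes (%d risk, %d protective)\n",
              x$name, nrow(x$genes), sum(x$genes$direction == 1),
              sum(x$genes$direction == -1)))
  invisible(x)
}

#' @export
length.gene_signature <- function(x) nrow(x$genes)

#' Selection thresholds for cross-cancer signature discovery
#'
#' @param fdr_max maximum Benjamini-Hochberg q-value, applied within each
#'   cancer type's scan.
#' @param hr_upper,hr_lower a gene must have pooled HR above `hr_upper` or
#'   below `hr_lower` (in every cancer type) to qualify.
#' @param require_concordance require the HR side (risk vs protective) to
#'   agree across cancer types.
#' @param holdout_dataset_ids datasets excluded from training scans (carried
#'   as metadata; the exclusion itself happens when building the training
#'   collection).
#' @return list of class `"selection_config"`.
#' @export
selection_config <- function(fdr_max = 0.05, hr_upper = 1.125,
                             hr_lower = 0.875, require_concordance = TRUE,
                             holdout_dataset_ids = character()) {
  stopifnot(fdr_max > 0, fdr_max < 1, hr_lower < 1, hr_upper > 1)
  structure(list(fdr_max = fdr_max, hr_upper = hr_upper, hr_lower = hr_lower,
                 require_concordance = require_concordance,
                 holdout_dataset_ids = holdout_dataset_ids),
            class = "selection_config")
}

#' Discover a cross-cancer prognostic signature
#'
#' A gene enters the signature iff, in every cancer type's training scan, its
#' q-value is below `fdr_max` and its pooled hazard ratio is above `hr_upper`
#' or below `hr_lower`; with `require_concordance` the HR side must agree
#' across cancer types. Directions are +1 for pooled HR > 1 and -1 otherwise.
#'
#' @param meta_by_cancer named list of `"meta_scan"` tables, one per cancer
#'   type (at least two).
#' @param config a [selection_config()].
#' @param name name for the resulting signature.
#' @return a `"gene_signature"` (possibly empty, with a warning); provenance
#'   records each selected gene's per-cancer HR and q.
#' @export
discover_signature <- function(meta_by_cancer, config = selection_config(),
                               name = "discovered") {
  if (length(meta_by_cancer) < 2)
    stop("signature discovery requires at least two cancer types")
  if (is.null(names(meta_by_cancer)))
    names(meta_by_cancer) <- paste0("cancer", seq_along(meta_by_cancer))
  passes <- lapply(meta_by_cancer, function(tab) {
    ok <- !is.na(tab$q) & tab$q < config$fdr_max &
      (tab$hr > config$hr_upper | tab$hr < config$hr_lower)
    tab[ok, c("gene", "hr", "q"), drop = FALSE]
  })
  genes <- Reduce(intersect, lapply(passes, `[[`, "gene"))
  genes <- sort(genes)                       # invariant to input gene order
  if (length(genes) && config$require_concordance) {
    side <- sapply(passes, function(tab) tab$hr[match(genes, tab$gene)] > 1)
    side <- matrix(side, nrow = length(genes))
    concordant <- rowSums(side) %in% c(0, ncol(side))
    genes <- genes[concordant]
  }
  if (length(genes) == 0) {
    warning("no genes pass the selection thresholds; empty signature")
    sig <- structure(
      list(name = name,
           genes = data.frame(gene = character(), direction = integer()),
           provenance = NULL),
      class = "gene_signature")
    return(sig)
  }
  hrs <- sapply(passes, function(tab) tab$hr[match(genes, tab$gene)])
  hrs <- matrix(hrs, nrow = length(genes),
                dimnames = list(genes, names(meta_by_cancer)))
  direction <- ifelse(rowMeans(log(hrs)) > 0, 1L, -1L)
  prov <- do.call(rbind, lapply(names(passes), function(type) {
    tab <- passes[[type]]
    i <- match(genes, tab$gene)
    data.frame(gene = genes, cancer_type = type, hr = tab$hr[i], q = tab$q[i],
               stringsAsFactors = FALSE)
  }))
  gene_signature(genes, direction, name = name, provenance = prov)
}

# Standardize an expression matrix within a dataset for scoring.
# zscore: per-gene (x - mean) / sd; rank: per-gene ranks mapped to [-1, 1].
standardize_expression <- function(mat, method = c("zscore", "rank")) {
  method <- match.arg(method)
  if (method == "zscore") {
    mu <- rowMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 1, sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- NA
    (mat - mu) / sdv
  } else {
    t(apply(mat, 1, function(x) {
      r <- rank(x, ties.method = "average", na.last = "keep")
      n <- sum(!is.na(x))
      if (n < 2) return(x * NA)
      2 * (r - 1) / (n - 1) - 1
    }))
  }
}

# Score samples from an already standardized matrix.
score_from_standardized <- function(zmat, genes, directions) {
  present <- genes %in% rownames(zmat)
  if (!any(present)) return(NULL)
  zs <- zmat[genes[present], , drop = FALSE] * directions[present]
  n_meas <- colSums(!is.na(zs))
  score <- ifelse(n_meas > 0, colSums(zs, na.rm = TRUE) / n_meas, NA)
  attr(score, "coverage") <- mean(present)
  score
}

#' Signed-average signature score
#'
#' Per-sample risk score: expression is standardized per gene within the
#' dataset, multiplied by the gene's +/-1 direction, and averaged over the
#' signature genes measured for that sample. Missing signature genes are
#' dropped from the denominator, keeping scores comparable across platforms.
#'
#' @param dataset an `expression_dataset` (gene-collapsed: row names are gene
#'   ids matching the signature).
#' @param signature a `"gene_signature"`.
#' @param method `"zscore"` (per-gene z-score within the dataset) or
#'   `"rank"` (per-gene ranks rescaled to \[-1, 1\]).
#' @return named numeric vector of per-sample scores with a `"coverage"`
#'   attribute (fraction of signature genes measured); a warning is issued
#'   when coverage falls below 50%.
#' @export
signed_average_score <- function(dataset, signature,
                                 method = c("zscore", "rank")) {
  if (nrow(signature$genes) == 0) stop("empty signature")
  zmat <- standardize_expression(dataset$exprs, method = method)
  score <- score_from_standardized(zmat, signature$genes$gene,
                                   signature$genes$direction)
  if (is.null(score))
    stop(sprintf("no signature gene measured in dataset %s", dataset$dataset_id))
  if (attr(score, "coverage") < 0.5)
    warning(sprintf("signature coverage %.0f%% in dataset %s",
                    100 * attr(score, "coverage"), dataset$dataset_id))
  score
}

#' Pooled meta D-index of a signature over a collection
#'
#' Scores every dataset by [signed_average_score()], computes the per-dataset
#' D-index of the scores against the endpoint, and pools the per-dataset
#' estimates with [combine_estimates()].
#'
#' @param collection a `cohort_collection`.
#' @param signature a `"gene_signature"`.
#' @param endpoint,model as in [genomewide_meta()].
#' @param method scoring method, see [signed_average_score()].
#' @return a `"meta_estimate"` with a `"per_dataset"` attribute (data frame
#'   of the per-dataset D-indices).
#' @export
meta_dindex <- function(collection, signature, endpoint = "overall_survival",
                        model = "random", method = "zscore") {
  rows <- list()
  for (co in collection) {
    ep <- extract_endpoint(co$clinical, endpoint)
    if (nrow(ep) < 3 || sum(ep$event) < 2) next
    score <- tryCatch(
      suppressWarnings(signed_average_score(co$expr, signature, method = method)),
      error = function(e) NULL)
    if (is.null(score)) next
    d <- tryCatch(d_index(score[ep$sample_id], ep$time, ep$event),
                  error = function(e) NULL)
    if (is.null(d)) next
    rows[[co$expr$dataset_id]] <- data.frame(
      dataset_id = co$expr$dataset_id, log_hr = d$log_hr, se = d$se,
      n = d$n, n_events = d$n_events, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("signature not scorable in any dataset")
  per_ds <- do.call(rbind, c(rows, make.row.names = FALSE))
  m <- combine_estimates(per_ds$log_hr, per_ds$se, model = model)
  attr(m, "per_dataset") <- per_ds
  m
}

#' Random-signature permutation null
#'
#' Tests whether a signature's pooled |D| exceeds what same-sized signatures
#' of randomly chosen genes achieve on the same collection. Random gene sets
#' are drawn uniformly from genes measured in every dataset of the
#' collection; by default each random gene inherits its direction from the
#' sign of its training pooled log-HR, so the null signatures are "trained
#' identically, but on random genes".
#'
#' @param collection evaluation cohorts (typically held out from training).
#' @param training_meta a `"meta_scan"` (or data frame with `gene`,
#'   `log_hr`) from the training collection, supplying directions.
#' @param signature the `"gene_signature"` under test.
#' @param n_random number of random signatures.
#' @param seed RNG seed (the null distribution is reproducible given the
#'   seed).
#' @param size size of the random signatures; defaults to the tested
#'   signature's size.
#' @param directions `"trained"` (from training hazard signs) or `"random"`
#'   (coin-flip).
#' @param endpoint,model,method as in [meta_dindex()].
#' @return object of class `"random_signature_null"`: `p` (add-one
#'   permutation p-value on |log HR|), `observed` (pooled log-HR of
#'   `signature`), `null_distribution`, `n_random`, `seed`.
#' @export
random_signature_null <- function(collection, training_meta, signature,
                                  n_random = 1000, seed = 1,
                                  size = nrow(signature$genes),
                                  directions = c("trained", "random"),
                                  endpoint = "overall_survival",
                                  model = "random", method = "zscore") {
  directions <- match.arg(directions)
  stopifnot(size >= 1, n_random >= 1)
  pool <- Reduce(intersect, lapply(collection,
                                   function(co) rownames(co$expr$exprs)))
  pool <- intersect(pool, training_meta$gene)
  if (size > length(pool))
    stop(sprintf("requested signature size %d exceeds the %d available genes",
                 size, length(pool)))
  trained_dir <- ifelse(training_meta$log_hr[match(pool, training_meta$gene)] >= 0,
                        1L, -1L)
  names(trained_dir) <- pool

  # precompute per-dataset standardized matrices and risk-set structures
  ctx <- list()
  for (co in collection) {
    ep <- extract_endpoint(co$clinical, endpoint)
    if (nrow(ep) < 3 || sum(ep$event) < 2) next
    zmat <- standardize_expression(co$expr$exprs[, ep$sample_id, drop = FALSE])
    ctx[[co$expr$dataset_id]] <- list(zmat = zmat, prep = cox_prep(ep$time, ep$event))
  }
  if (length(ctx) == 0) stop("no dataset with enough events")

  meta_abs <- function(genes, dirs) {
    est <- vapply(ctx, function(cc) {
      sc <- score_from_standardized(cc$zmat, genes, dirs)
      if (is.null(sc)) return(c(NA_real_, NA_real_))
      dindex_core(sc, cc$prep)
    }, numeric(2))
    ok <- !is.na(est[1, ])
    if (!any(ok)) return(NA_real_)
    combine_estimates(est[1, ok], est[2, ok], model = model)$pooled_log_hr
  }

  observed <- meta_dindex(collection, signature, endpoint = endpoint,
                          model = model, method = method)$pooled_log_hr
  set.seed(seed)
  null_dist <- vapply(seq_len(n_random), function(b) {
    g <- sample(pool, size)
    d <- if (directions == "trained") trained_dir[g]
         else sample(c(-1L, 1L), size, replace = TRUE)
    meta_abs(g, d)
  }, 0)
  p <- (1 + sum(abs(null_dist) >= abs(observed), na.rm = TRUE)) / (n_random + 1)
  structure(
    list(p = p, observed = observed, null_distribution = null_dist,
         n_random = n_random, seed = seed, size = size),
    class = "random_signature_null"
  )
}

#' @export
print.random_signature_null <- function(x, ...) {
  cat(sprintf(
    "Random-signature null: observed |log HR| = %.4f vs %d random signatures of size %d\n",
    abs(x$observed), x$n_random, x$size))
  cat(sprintf("  permutation p = %.4g (seed %d)\n", x$p, x$seed))
  invisible(x)
}

#' Write a random-signature null report to TSV
#'
#' @param x a `"random_signature_null"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_null_report <- function(x, path) {
  qs <- quantile(abs(x$null_distribution), c(0.5, 0.9, 0.95, 0.99), na.rm = TRUE)
  df <- data.frame(observed_log_hr = x$observed, p = x$p,
                   n_random = x$n_random, seed = x$seed,
                   null_q50 = qs[1], null_q90 = qs[2], null_q95 = qs[3],
                   null_q99 = qs[4])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene signature as JSON
#'
#' The JSON layout is `{name, genes: [{symbol, entrez_id, direction}, ...]}`.
#'
#' @param path file path.
#' @return for `read_signature`, a `"gene_signature"` (with an
#'   `"annotation"` attribute carrying symbols/Entrez ids when present).
#' @export
read_signature <- function(path) {
  obj <- jsonlite::fromJSON(path)
  genes <- obj$genes
  sig <- gene_signature(genes$symbol, genes$direction, name = obj$name)
  attr(sig, "annotation") <- genes
  sig
}

#' @rdname read_signature
#' @param signature a `"gene_signature"`.
#' @export
write_signature <- function(signature, path) {
  ann <- attr(signature, "annotation")
  genes <- data.frame(symbol = signature$genes$gene,
                      entrez_id = if (!is.null(ann)) ann$entrez_id else NA,
                      direction = signature$genes$direction)
  jsonlite::write_json(list(name = signature$name, genes = genes), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Bundled reference gene sets
#'
#' `metagx_signature()` returns the published 53-gene multi-cancer (MetaGx)
#' signature with its +/-1 directions; `ovarian_prognostic_genes()` the six
#' well-studied ovarian prognostic genes; `breast_module_prototypes()` the
#' seven breast cancer gene-module prototype genes.
#'
#' @return `metagx_signature()`: a `"gene_signature"`; the others: character
#'   vectors.
#' @export
metagx_signature <- function() {
  read_signature(system.file("extdata", "metagx_signature.json",
                             package = "metasig", mustWork = TRUE))
}

#' @rdname metagx_signature
#' @export
ovarian_prognostic_genes <- function() {
  jsonlite::fromJSON(system.file("extdata", "reference_gene_sets.json",
                                 package = "metasig", mustWork = TRUE))$ovarian_prognostic_genes
}

#' @rdname metagx_signature
#' @export
breast_module_prototypes <- function() {
  jsonlite::fromJSON(system.file("extdata", "reference_gene_sets.json",
                                 package = "metasig", mustWork = TRUE))$breast_module_prototypes
}
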