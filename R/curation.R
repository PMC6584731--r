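# Standardization filters applied before any analysis: probe-to-gene
# collapsing by maximal interquartile range, duplicate-sample removal by
# Spearman correlation within a cancer type, and sample-type / cohort-size
# filtering.

#' Collapse probes to genes by maximal interquartile range
#'
#' For genes measured by several probes, only the probe with the largest IQR
#' of expression across the dataset is retained; probes mapping to no gene
#' (neither symbol nor Entrez id) are dropped. Ties in IQR are broken by
#' annotation order. The gene key is the gene symbol where present,
#' otherwise `ENTREZ:<id>`.
#'
#' @param dataset an `expression_dataset`.
#' @return an `expression_dataset` with one row per gene; the chosen probe
#'   per gene is recorded in the `"provenance"` attribute (a data frame with
#'   columns `gene`, `probe_id`, `iqr`).
#' @export
collapse_probes <- function(dataset) {
  feats <- dataset$features
  key <- ifelse(!is.na(feats$gene_symbol), feats$gene_symbol,
                ifelse(!is.na(feats$entrez_id),
                       paste0("ENTREZ:", feats$entrez_id), NA))
  mappable <- !is.na(key)
  if (!any(mappable))
    stop("no gene-mappable probes in dataset ", dataset$dataset_id)
  iqr <- apply(dataset$exprs, 1, IQR, na.rm = TRUE)
  iqr[is.na(iqr)] <- -Inf
  idx <- which(mappable)
  # stable per-gene argmax: annotation order wins ties because which.max
  # returns the first maximum
  chosen <- vapply(split(idx, key[idx]),
                   function(rows) rows[which.max(iqr[rows])], 0L)
  chosen <- chosen[order(chosen)]          # keep original row order
  out <- dataset$exprs[chosen, , drop = FALSE]
  rownames(out) <- key[chosen]
  features <- data.frame(
    probe_id = key[chosen],
    gene_symbol = feats$gene_symbol[chosen],
    entrez_id = feats$entrez_id[chosen],
    stringsAsFactors = FALSE
  )
  res <- expression_dataset(out, features, dataset_id = dataset$dataset_id,
                            cancer_type = dataset$cancer_type)
  attr(res, "provenance") <- data.frame(
    gene = key[chosen], probe_id = feats$probe_id[chosen], iqr = iqr[chosen],
    row.names = NULL, stringsAsFactors = FALSE
  )
  res
}

# Spearman correlation matrix between sample columns over shared genes.
# Ranks are computed per column over its non-missing entries, then Pearson
# correlation on pairwise-complete pairs.
spearman_columns <- function(mat) {
  ranked <- apply(mat, 2, rank, ties.method = "average", na.last = "keep")
  suppressWarnings(cor(ranked, use = "pairwise.complete.obs"))
}

#' Remove duplicated samples by Spearman correlation
#'
#' Flags sample pairs whose expression profiles over shared genes have
#' Spearman rho above `rho_threshold`, within and across datasets of the same
#' cancer type, and removes one member per excess: among each connected
#' component of the rho-graph exactly one sample is kept (the member from the
#' largest dataset, ties broken by lexicographically smallest sample id).
#' A pair is only scored when at least `min_shared_genes` genes are
#' non-missing in both profiles.
#'
#' @param collection a `cohort_collection`, gene-collapsed so that datasets of
#'   one cancer type share a gene space.
#' @param rho_threshold Spearman correlation above which a pair counts as a
#'   replicate; must lie in (0, 1].
#' @param min_shared_genes minimum number of pairwise-complete genes needed
#'   to score a pair.
#' @return list with `collection` (duplicates removed) and `report` (data
#'   frame `kept_id`, `removed_id`, `rho`, `cancer_type`, one row per flagged
#'   pair).
#' @export
remove_duplicates <- function(collection, rho_threshold = 0.98,
                              min_shared_genes = 30) {
  if (!(rho_threshold > 0 && rho_threshold <= 1))
    stop("rho_threshold must lie in (0, 1]")
  grouping <- attr(collection, "grouping")
  report <- list()
  drop <- character()

  for (type in names(grouping)) {
    ids <- grouping[[type]]
    genes <- Reduce(intersect, lapply(collection[ids],
                                      function(co) rownames(co$expr$exprs)))
    if (length(genes) < min_shared_genes) next
    mats <- lapply(collection[ids], function(co) co$expr$exprs[genes, , drop = FALSE])
    big <- do.call(cbind, unname(mats))
    origin <- rep(ids, vapply(mats, ncol, 0))
    sizes <- setNames(vapply(mats, ncol, 0), ids)

    n_ok <- crossprod(!is.na(big))           # shared non-missing genes per pair
    rho <- spearman_columns(big)
    rho[n_ok < min_shared_genes] <- NA
    diag(rho) <- NA
    hits <- which(rho > rho_threshold, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) == 0) next

    # connected components via union-find over flagged samples
    nodes <- sort(unique(c(hits[, 1], hits[, 2])))
    parent <- setNames(nodes, nodes)
    find <- function(i) { while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]; i }
    for (r in seq_len(nrow(hits))) {
      a <- find(hits[r, 1]); b <- find(hits[r, 2])
      if (a != b) parent[[as.character(a)]] <- b
    }
    comp <- vapply(nodes, find, 0)
    type_drop <- character()
    for (cc in unique(comp)) {
      members <- nodes[comp == cc]
      pri <- order(-sizes[origin[members]], colnames(big)[members])
      type_drop <- c(type_drop, colnames(big)[members[pri[-1]]])
    }
    drop <- c(drop, type_drop)
    # per flagged pair, report which member survives; in a component of
    # three or more mutual replicates both members of some pairs are removed,
    # in which case the first column is reported as "kept" for that pair
    id1 <- colnames(big)[hits[, 1]]
    id2 <- colnames(big)[hits[, 2]]
    kept <- ifelse(id1 %in% type_drop & !(id2 %in% type_drop), id2, id1)
    removed <- ifelse(kept == id1, id2, id1)
    report[[type]] <- data.frame(kept_id = kept, removed_id = removed,
                                 rho = rho[hits], cancer_type = type,
                                 stringsAsFactors = FALSE)
  }

  report <- if (length(report)) do.call(rbind, c(report, make.row.names = FALSE))
            else data.frame(kept_id = character(), removed_id = character(),
                            rho = numeric(), cancer_type = character())
  if (length(drop)) {
    cohorts <- lapply(collection, function(co) {
      keep <- !(colnames(co$expr$exprs) %in% drop)
      if (all(keep)) return(co)
      subset_cohort(co, colnames(co$expr$exprs)[keep])
    })
    collection <- cohort_collection(cohorts)
  }
  list(collection = collection, report = report)
}

# Restrict one cohort to a subset of sample ids.
subset_cohort <- function(co, sample_ids) {
  expr <- expression_dataset(co$expr$exprs[, sample_ids, drop = FALSE],
                             co$expr$features, dataset_id = co$expr$dataset_id,
                             cancer_type = co$expr$cancer_type)
  clinical <- co$clinical[match(sample_ids, co$clinical$sample_id), ]
  rownames(clinical) <- NULL
  class(clinical) <- c("clinical_table", "data.frame")
  list(expr = expr, clinical = clinical)
}

#' Write a duplicate-removal report to TSV
#'
#' @param report the `report` component of [remove_duplicates()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_duplicate_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a collection by sample type and cohort size
#'
#' Optionally drops non-tumor samples, then drops whole datasets that fall
#' below a minimum sample count or a minimum number of events on the chosen
#' endpoint.
#'
#' @param collection a `cohort_collection`.
#' @param min_samples,min_events minimum post-filter sample and event counts
#'   a dataset must retain.
#' @param tumor_only drop samples whose `sample_type` is not `"tumor"`.
#' @param endpoint endpoint on which events are counted.
#' @return filtered `cohort_collection`; the decisions taken are recorded in
#'   the `"filter_log"` attribute.
#' @export
filter_collection <- function(collection, min_samples = 0, min_events = 0,
                              tumor_only = TRUE,
                              endpoint = "overall_survival") {
  log <- character()
  kept <- list()
  for (co in collection) {
    id <- co$expr$dataset_id
    if (tumor_only) {
      tum <- co$clinical$sample_id[co$clinical$sample_type %in% "tumor"]
      n_drop <- ncol(co$expr$exprs) - length(tum)
      if (n_drop > 0) {
        log <- c(log, sprintf("%s: removed %d non-tumor samples", id, n_drop))
        if (length(tum) == 0) {
          log <- c(log, sprintf("%s: dropped (no tumor samples)", id))
          next
        }
        co <- subset_cohort(co, tum)
      }
    }
    if (ncol(co$expr$exprs) < min_samples) {
      log <- c(log, sprintf("%s: dropped (%d samples < %d)", id,
                            ncol(co$expr$exprs), min_samples))
      next
    }
    n_ev <- sum(extract_endpoint(co$clinical, endpoint)$event)
    if (n_ev < min_events) {
      log <- c(log, sprintf("%s: dropped (%d events < %d)", id, n_ev, min_events))
      next
    }
    kept[[id]] <- co
  }
  if (length(kept) == 0)
    warning("no datasets survive filtering")
  out <- cohort_collection(kept)
  attr(out, "filter_log") <- log
  out
}
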