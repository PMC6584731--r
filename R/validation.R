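# Evaluation of signatures on held-out cohorts: overall and
# subtype-stratified pooled D-index and log-rank tests, and random-effects
# meta-correlations between signature scores and gene-module scores.

#' Construct a gene module
#'
#' A gene module is a prototype gene (e.g. AURKA for proliferation) plus
#' member genes with +/-1 directions, scored by the same signed-average
#' machinery as signatures.
#'
#' @param prototype prototype gene id; added to the members if absent.
#' @param genes,directions member genes and directions as in
#'   [gene_signature()].
#' @return a `"gene_module"` (also a `"gene_signature"`).
#' @export
gene_module <- function(prototype, genes = prototype, directions = 1) {
  directions <- rep_len(as.integer(directions), length(genes))
  if (!prototype %in% genes) {
    genes <- c(prototype, genes)
    directions <- c(1L, directions)
  }
  sig <- gene_signature(genes, directions, name = prototype)
  sig$prototype <- prototype
  class(sig) <- c("gene_module", "gene_signature")
  sig
}

# Pooled evaluation of one score stratum across datasets: per-dataset
# D-index + median split, pooled meta D and pooled log-rank on the
# concatenated groups.
evaluate_stratum <- function(scores_by_ds, endpoints_by_ds, model = "random") {
  est <- list(); grp <- list(); tim <- list(); evt <- list()
  for (id in names(scores_by_ds)) {
    sc <- scores_by_ds[[id]]
    ep <- endpoints_by_ds[[id]]
    keep <- ep$sample_id %in% names(sc)
    ep <- ep[keep, , drop = FALSE]
    if (nrow(ep) < 3 || sum(ep$event) < 2) next
    sc <- sc[ep$sample_id]
    d <- tryCatch(d_index(sc, ep$time, ep$event), error = function(e) NULL)
    if (is.null(d)) next
    est[[id]] <- c(d$log_hr, d$se, d$n, d$n_events)
    grp[[id]] <- median_split(sc)
    tim[[id]] <- ep$time
    evt[[id]] <- ep$event
  }
  if (length(est) == 0) return(NULL)
  em <- do.call(rbind, est)
  meta <- combine_estimates(em[, 1], em[, 2], model = model)
  groups <- unlist(grp); time <- unlist(tim); event <- unlist(evt)
  lr <- if (length(unique(groups)) == 2 && sum(event) >= 1)
    logrank_test(groups, time, event) else list(chi2 = NA_real_, p = NA_real_)
  list(meta = meta, logrank = lr, n = sum(em[, 3]), n_events = sum(em[, 4]),
       k = nrow(em))
}

#' Evaluate a signature on a collection, overall and per subtype
#'
#' Scores each dataset with [signed_average_score()] (standardizing on the
#' full dataset), then for the `"all"` stratum and each subtype label:
#' per-dataset D-index of the scores, pooled by [combine_estimates()];
#' per-dataset median split, pooled across datasets into a single log-rank
#' test on the concatenated groups. Strata with fewer than 2 events in every
#' dataset are skipped with a warning.
#'
#' @param collection a `cohort_collection` (e.g. held-out cohorts).
#' @param signature a `"gene_signature"` (or `"gene_module"`).
#' @param strata `"subtype"` to stratify by the clinical subtype column,
#'   `NULL` for the overall analysis only, or a character vector of subtype
#'   labels to evaluate.
#' @param endpoint,model,method as in [meta_dindex()].
#' @return data frame of class `"signature_evaluation"`: one row per stratum
#'   with `signature`, `stratum`, `k`, `log_hr`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`, `d_p`, `logrank_chi2`, `logrank_p`, `n`, `n_events`.
#' @export
evaluate_signature <- function(collection, signature, strata = "subtype",
                               endpoint = "overall_survival",
                               model = "random", method = "zscore") {
  scores_by_ds <- list(); endpoints_by_ds <- list(); subtype_by_sample <- list()
  for (co in collection) {
    ep <- extract_endpoint(co$clinical, endpoint)
    if (nrow(ep) == 0) next
    sc <- tryCatch(
      suppressWarnings(signed_average_score(co$expr, signature, method = method)),
      error = function(e) NULL)
    if (is.null(sc)) next
    id <- co$expr$dataset_id
    scores_by_ds[[id]] <- sc
    endpoints_by_ds[[id]] <- ep
    subtype_by_sample[[id]] <- setNames(co$clinical$subtype, co$clinical$sample_id)
  }
  if (length(scores_by_ds) == 0) stop("signature not scorable in any dataset")

  labels <- "all"
  if (identical(strata, "subtype")) {
    labels <- c("all", sort(unique(na.omit(unlist(subtype_by_sample)))))
  } else if (is.character(strata) && length(strata) > 0 && !identical(strata, "subtype")) {
    labels <- unique(c("all", strata))
  }

  rows <- list()
  for (stratum in labels) {
    sc_s <- scores_by_ds
    if (stratum != "all") {
      sc_s <- lapply(names(sc_s), function(id) {
        keep <- names(scores_by_ds[[id]]) %in%
          names(which(subtype_by_sample[[id]] == stratum))
        scores_by_ds[[id]][keep]
      })
      names(sc_s) <- names(scores_by_ds)
    }
    ev <- evaluate_stratum(sc_s, endpoints_by_ds, model = model)
    if (is.null(ev)) {
      warning(sprintf("stratum '%s' skipped: fewer than 2 events in every dataset",
                      stratum))
      next
    }
    m <- ev$meta
    rows[[stratum]] <- data.frame(
      signature = signature$name, stratum = stratum, k = ev$k,
      log_hr = m$pooled_log_hr, se = m$pooled_se, hr = m$hr,
      ci_lo = m$ci95[1], ci_hi = m$ci95[2], d_p = m$p_value,
      logrank_chi2 = ev$logrank$chi2, logrank_p = ev$logrank$p,
      n = ev$n, n_events = ev$n_events, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("signature_evaluation", "data.frame")
  out
}

#' @export
print.signature_evaluation <- function(x, ...) {
  cat(sprintf("<signature_evaluation> %s\n", x$signature[1]))
  print.data.frame(as.data.frame(x)[c("stratum", "k", "hr", "ci_lo", "ci_hi",
                                      "d_p", "logrank_p", "n")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a signature evaluation to TSV
#'
#' @param evaluation a `"signature_evaluation"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_evaluation <- function(evaluation, path) {
  write.table(as.data.frame(evaluation), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Meta-correlation between signature scores and gene-module scores
#'
#' Per dataset, the Spearman correlation between the signature's and each
#' module's signed-average scores; correlations are Fisher-z transformed
#' (|rho| clipped at 0.9999 to avoid infinities), given standard error
#' `1/sqrt(n - 3)`, pooled by [combine_estimates()] and back-transformed.
#' Datasets with fewer than 4 scorable samples are skipped.
#'
#' @param collection a `cohort_collection`.
#' @param signature a `"gene_signature"`.
#' @param modules list of `"gene_module"` (or signature) objects.
#' @param model,method as in [meta_dindex()].
#' @return data frame of class `"module_correlation"`: `module`, `k`, `rho`
#'   (pooled), `ci_lo`, `ci_hi`, `p`.
#' @export
correlate_with_modules <- function(collection, signature, modules,
                                   model = "random", method = "zscore") {
  clip <- 0.9999
  sig_scores <- lapply(collection, function(co) tryCatch(
    suppressWarnings(signed_average_score(co$expr, signature, method = method)),
    error = function(e) NULL))
  rows <- lapply(modules, function(mod) {
    zs <- c(); ses <- c()
    for (i in seq_along(collection)) {
      ssc <- sig_scores[[i]]
      if (is.null(ssc)) next
      msc <- tryCatch(
        suppressWarnings(signed_average_score(collection[[i]]$expr, mod,
                                              method = method)),
        error = function(e) NULL)
      if (is.null(msc)) next
      ok <- !(is.na(ssc) | is.na(msc))
      if (sum(ok) < 4) next
      rho <- cor(ssc[ok], msc[ok], method = "spearman")
      rho <- max(min(rho, clip), -clip)
      zs <- c(zs, atanh(rho))
      ses <- c(ses, 1 / sqrt(sum(ok) - 3))
    }
    if (length(zs) == 0) return(NULL)
    m <- combine_estimates(zs, ses, model = model)
    zcrit <- qnorm(0.975)
    data.frame(module = mod$name, k = m$k, rho = tanh(m$pooled_log_hr),
               ci_lo = tanh(m$pooled_log_hr - zcrit * m$pooled_se),
               ci_hi = tanh(m$pooled_log_hr + zcrit * m$pooled_se),
               p = m$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, TRUE)],
                          make.row.names = FALSE))
  class(out) <- c("module_correlation", "data.frame")
  out
}

#' @export
print.module_correlation <- function(x, ...) {
  cat("<module_correlation>\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
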