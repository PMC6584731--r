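# Pooling of per-dataset log-hazard estimates into per-gene meta-estimates
# with DerSimonian-Laird between-study variance, plus the genome-wide scan
# with Benjamini-Hochberg FDR control.

#' Combine per-study estimates into a meta-estimate
#'
#' Inverse-variance pooling of independent estimates. Under the fixed-effects
#' model the weights are `1/se^2`. Under the random-effects model the
#' DerSimonian-Laird between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` (with `Q`
#' Cochran's heterogeneity statistic on fixed weights) is added to each
#' study's variance before weighting. The p-value is a two-sided normal test
#' of the pooled z-score.
#'
#' @param log_hr,se numeric vectors of per-study estimates (any scale on
#'   which estimates combine additively) and their standard errors (> 0).
#' @param model `"random"` (default) or `"fixed"`.
#' @return object of class `"meta_estimate"`: `pooled_log_hr`, `pooled_se`,
#'   `hr`, `ci95`, `p_value`, `tau2`, `cochran_q`, `k`, `model`.
#' @export
combine_estimates <- function(log_hr, se, model = c("random", "fixed")) {
  model <- match.arg(model)
  keep <- !(is.na(log_hr) | is.na(se))
  log_hr <- log_hr[keep]; se <- se[keep]
  k <- length(log_hr)
  if (k == 0) stop("no estimates to combine")
  if (any(se <= 0)) stop("standard errors must be positive")

  w <- 1 / se^2
  mu_fixed <- sum(w * log_hr) / sum(w)
  q <- sum(w * (log_hr - mu_fixed)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0

  if (model == "random") {
    w_star <- 1 / (se^2 + tau2)
    pooled <- sum(w_star * log_hr) / sum(w_star)
    pooled_se <- 1 / sqrt(sum(w_star))
  } else {
    pooled <- mu_fixed
    pooled_se <- 1 / sqrt(sum(w))
  }
  z <- pooled / pooled_se
  structure(
    list(pooled_log_hr = pooled, pooled_se = pooled_se, hr = exp(pooled),
         ci95 = exp(pooled + c(-1, 1) * qnorm(0.975) * pooled_se),
         p_value = 2 * pnorm(-abs(z)), tau2 = tau2, cochran_q = q,
         k = k, model = model),
    class = "meta_estimate"
  )
}

#' @export
print.meta_estimate <- function(x, ...) {
  cat(sprintf(
    "Meta-estimate (%s effects, k = %d): %.4f (se %.4f), HR %.3f (95%% CI %.3f-%.3f)\n",
    x$model, x$k, x$pooled_log_hr, x$pooled_se, x$hr, x$ci95[1], x$ci95[2]))
  cat(sprintf("  p = %.3g, tau2 = %.4g, Cochran Q = %.3f\n",
              x$p_value, x$tau2, x$cochran_q))
  invisible(x)
}

#' @export
coef.meta_estimate <- function(object, ...) c(pooled_log_hr = object$pooled_log_hr)

#' @export
confint.meta_estimate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  matrix(object$pooled_log_hr + c(-1, 1) * z * object$pooled_se, 1,
         dimnames = list("pooled_log_hr", c("lo", "hi")))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment with enforced monotonicity
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p_values) {
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  p.adjust(p_values, method = "BH")
}

# Per-dataset D-index of every gene row of a dataset against an endpoint.
# Returns a data frame gene/log_hr/se (NA rows dropped).
scan_dataset <- function(co, endpoint = "overall_survival", genes = NULL) {
  ep <- extract_endpoint(co$clinical, endpoint)
  if (nrow(ep) < 3 || sum(ep$event) < 2) return(NULL)
  mat <- co$expr$exprs[, ep$sample_id, drop = FALSE]
  if (!is.null(genes)) mat <- mat[intersect(rownames(mat), genes), , drop = FALSE]
  if (nrow(mat) == 0) return(NULL)
  prep <- cox_prep(ep$time, ep$event)
  est <- matrix(NA_real_, nrow(mat), 2)
  complete <- !is.na(rowSums(mat))
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (!complete[i]) {
      keep <- !is.na(x)
      if (sum(keep) < 3 || sum(ep$event[keep]) < 2) next
      sub_prep <- cox_prep(ep$time[keep], ep$event[keep])
      est[i, ] <- dindex_core(x[keep], sub_prep)
    } else {
      est[i, ] <- dindex_core(x, prep)
    }
  }
  ok <- !is.na(est[, 1])
  if (!any(ok)) return(NULL)
  data.frame(gene = rownames(mat)[ok], log_hr = est[ok, 1], se = est[ok, 2],
             n = nrow(ep), n_events = sum(ep$event), stringsAsFactors = FALSE)
}

#' Genome-wide prognostic meta-analysis
#'
#' For every gene measured in at least `min_datasets` datasets of the
#' collection, estimates the per-dataset D-index and pools the estimates with
#' [combine_estimates()]; q-values are Benjamini-Hochberg over the returned
#' gene set. Genes with degenerate per-dataset fits simply contribute fewer
#' studies (`k` is decremented).
#'
#' @param collection a `cohort_collection` (typically one cancer type,
#'   curated and gene-collapsed).
#' @param endpoint survival endpoint, as in [extract_endpoint()].
#' @param min_datasets minimum number of datasets a gene must be estimable in.
#' @param model pooling model for [combine_estimates()].
#' @param gene_universe `"threshold"` keeps every gene estimable in
#'   `min_datasets` datasets; `"intersection"` restricts to genes measured in
#'   every dataset.
#' @param cancer_type optional: restrict the scan to datasets of one type.
#' @return data frame of class `"meta_scan"` with one row per gene: `gene`,
#'   `k`, `log_hr`, `se`, `hr`, `ci_lo`, `ci_hi`, `p`, `q`, `tau2`,
#'   `cochran_q`.
#' @export
genomewide_meta <- function(collection, endpoint = "overall_survival",
                            min_datasets = 6, model = "random",
                            gene_universe = c("threshold", "intersection"),
                            cancer_type = NULL) {
  gene_universe <- match.arg(gene_universe)
  stopifnot(min_datasets >= 1)
  if (!is.null(cancer_type)) {
    ids <- unlist(attr(collection, "grouping")[cancer_type])
    collection <- cohort_collection(collection[ids])
  }
  genes <- NULL
  if (gene_universe == "intersection")
    genes <- Reduce(intersect, lapply(collection,
                                      function(co) rownames(co$expr$exprs)))
  per_ds <- lapply(collection, scan_dataset, endpoint = endpoint, genes = genes)
  per_ds <- per_ds[!vapply(per_ds, is.null, TRUE)]
  if (length(per_ds) == 0) return(empty_meta_scan())
  long <- do.call(rbind, c(per_ds, make.row.names = FALSE))

  split_gene <- split(seq_len(nrow(long)), long$gene)
  split_gene <- split_gene[lengths(split_gene) >= min_datasets]
  if (length(split_gene) == 0) return(empty_meta_scan())
  est <- vapply(split_gene, function(i) {
    m <- combine_estimates(long$log_hr[i], long$se[i], model = model)
    c(m$k, m$pooled_log_hr, m$pooled_se, m$p_value, m$tau2, m$cochran_q)
  }, numeric(6))
  zc <- qnorm(0.975)
  out <- data.frame(
    gene = names(split_gene), k = as.integer(est[1, ]), log_hr = est[2, ],
    se = est[3, ], hr = exp(est[2, ]),
    ci_lo = exp(est[2, ] - zc * est[3, ]), ci_hi = exp(est[2, ] + zc * est[3, ]),
    p = est[4, ], q = adjust_fdr(est[4, ]), tau2 = est[5, ],
    cochran_q = est[6, ], stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "endpoint") <- endpoint
  attr(out, "model") <- model
  attr(out, "datasets") <- names(per_ds)
  class(out) <- c("meta_scan", "data.frame")
  out
}

empty_meta_scan <- function() {
  out <- data.frame(gene = character(), k = integer(), log_hr = numeric(),
                    se = numeric(), hr = numeric(), ci_lo = numeric(),
                    ci_hi = numeric(), p = numeric(), q = numeric(),
                    tau2 = numeric(), cochran_q = numeric())
  class(out) <- c("meta_scan", "data.frame")
  out
}

#' @export
print.meta_scan <- function(x, ...) {
  cat(sprintf("<meta_scan> %d genes over %d datasets (%s effects)\n",
              nrow(x), length(attr(x, "datasets")), attr(x, "model")))
  cat(sprintf("  genes at q < 0.05: %d\n", sum(x$q < 0.05, na.rm = TRUE)))
  if (nrow(x) > 0) {
    top <- x[order(x$p), ][seq_len(min(5, nrow(x))), ]
    print.data.frame(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.meta_scan <- function(object, fdr_max = 0.05, ...) {
  sig <- object[!is.na(object$q) & object$q < fdr_max, ]
  list(n_genes = nrow(object), n_significant = nrow(sig),
       n_risk = sum(sig$hr > 1), n_protective = sum(sig$hr < 1),
       median_k = if (nrow(object)) median(object$k) else NA)
}

#' Forest-style plot of the strongest meta-estimates
#'
#' @param x a `"meta_scan"`.
#' @param n_top number of genes (by p-value) to display.
#' @param ... passed to [plot()].
#' @export
plot.meta_scan <- function(x, n_top = 20, ...) {
  if (nrow(x) == 0) stop("empty scan")
  top <- x[order(x$p), ][seq_len(min(n_top, nrow(x))), ]
  top <- top[rev(seq_len(nrow(top))), ]
  ylim <- c(0.5, nrow(top) + 0.5)
  xlim <- range(c(top$ci_lo, top$ci_hi, 1))
  plot(top$hr, seq_len(nrow(top)), log = "x", xlim = xlim, ylim = ylim,
       pch = 15, yaxt = "n", xlab = "hazard ratio (95% CI)", ylab = "", ...)
  segments(top$ci_lo, seq_len(nrow(top)), top$ci_hi, seq_len(nrow(top)))
  abline(v = 1, lty = 2)
  axis(2, at = seq_len(nrow(top)), labels = top$gene, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Write a genome-wide scan to TSV
#'
#' @param scan a `"meta_scan"`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_meta_scan <- function(scan, path) {
  write.table(as.data.frame(scan), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
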