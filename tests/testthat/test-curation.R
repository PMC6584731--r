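make_probe_dataset <- function(mat, gene_of_probe) {
  expression_dataset(
    mat,
    features = data.frame(probe_id = rownames(mat),
                          gene_symbol = gene_of_probe,
                          entrez_id = NA_integer_, stringsAsFactors = FALSE),
    dataset_id = "probes")
}

test_that("collapse_probes keeps the max-IQR probe and drops unmapped probes", {
  mat <- rbind(p1 = c(0, 2, 4, 6),     # IQR 3
               p2 = c(1, 1.2, 1.4, 1.6),  # IQR 0.3
               p3 = c(5, 5, 5, 5))
  colnames(mat) <- paste0("s", 1:4)
  ds <- make_probe_dataset(mat, c("G", "G", NA))
  out <- collapse_probes(ds)
  expect_identical(rownames(out$exprs), "G")
  expect_equal(unname(out$exprs["G", ]), unname(mat["p1", ]))
  expect_identical(attr(out, "provenance")$probe_id, "p1")
})

test_that("collapse_probes is the identity up to relabeling for 1-probe genes", {
  co <- make_cohort(n_genes = 8, n = 10, seed = 3)
  out <- collapse_probes(co$expr)
  expect_equal(unname(out$exprs), unname(co$expr$exprs))
  expect_true(all.equal(collapse_probes(out)$exprs, out$exprs))  # idempotent
})

test_that("collapse_probes matches a brute-force IQR argmax oracle", {
  set.seed(42)
  n_probes <- 10; n <- 25
  mat <- matrix(rnorm(n_probes * n, sd = rep(runif(n_probes, 0.2, 3), n)),
                n_probes, n,
                dimnames = list(paste0("p", 1:n_probes), paste0("s", 1:n)))
  gene_of_probe <- sample(c("A", "B", "C"), n_probes, replace = TRUE)
  ds <- make_probe_dataset(mat, gene_of_probe)
  out <- collapse_probes(ds)
  for (g in unique(gene_of_probe)) {
    probes <- rownames(mat)[gene_of_probe == g]
    iqrs <- vapply(probes, function(p)
      diff(quantile(mat[p, ], c(0.25, 0.75))), 0)
    best <- probes[which.max(iqrs)]
    expect_equal(unname(out$exprs[g, ]), unname(mat[best, ]))
  }
  expect_error(collapse_probes(make_probe_dataset(mat, rep(NA, n_probes))),
               "no gene-mappable")
})

test_that("remove_duplicates flags exact and constructed near-duplicates", {
  set.seed(9)
  n_genes <- 2000
  genes <- sprintf("G%04d", 1:n_genes)
  base <- matrix(rnorm(n_genes * 4), n_genes, 4,
                 dimnames = list(genes, paste0("a", 1:4)))
  # a4 duplicated into the second dataset under another name
  mat2 <- cbind(base[, 4, drop = FALSE], matrix(rnorm(n_genes * 2), n_genes))
  colnames(mat2) <- paste0("b", 1:3)
  mk <- function(mat, id) {
    n <- ncol(mat)
    list(expr = expression_dataset(mat, dataset_id = id),
         clinical = clinical_table(data.frame(
           sample_id = colnames(mat), dataset_id = id, sample_type = "tumor")))
  }
  coll <- cohort_collection(list(mk(base, "dsA"), mk(mat2, "dsB")))
  res <- remove_duplicates(coll)
  expect_equal(nrow(res$report), 1)
  expect_setequal(c(res$report$kept_id, res$report$removed_id), c("a4", "b1"))
  expect_equal(res$report$rho, 1)
  # kept member comes from the larger dataset
  expect_identical(res$report$kept_id, "a4")
  total_before <- 7; total_after <- sum(vapply(res$collection, function(co)
    ncol(co$expr$exprs), 0))
  expect_equal(total_after, total_before - 1)
  expect_error(remove_duplicates(coll, rho_threshold = 1.5), "rho_threshold")
})

test_that("near-duplicate rho matches the brute-force Spearman oracle", {
  set.seed(11)
  n_genes <- 2000
  latent <- rnorm(n_genes)
  w <- 0.993
  a <- sqrt(w) * latent + sqrt(1 - w) * rnorm(n_genes)
  b <- sqrt(w) * latent + sqrt(1 - w) * rnorm(n_genes)
  indep <- matrix(rnorm(n_genes * 2), n_genes, 2)
  mat <- cbind(a, b, indep)
  dimnames(mat) <- list(sprintf("G%04d", 1:n_genes), c("s1", "s2", "s3", "s4"))
  rho_ab <- oracle_spearman(mat[, "s1"], mat[, "s2"])
  expect_gt(rho_ab, 0.98)
  expect_lt(abs(oracle_spearman(mat[, "s3"], mat[, "s4"])), 0.2)
  coll <- cohort_collection(list(list(
    expr = expression_dataset(mat, dataset_id = "d1"),
    clinical = clinical_table(data.frame(sample_id = colnames(mat),
                                         dataset_id = "d1",
                                         sample_type = "tumor")))))
  res <- remove_duplicates(coll)
  expect_equal(nrow(res$report), 1)
  expect_setequal(c(res$report$kept_id, res$report$removed_id), c("s1", "s2"))
  expect_equal(res$report$rho, rho_ab, tolerance = 1e-12)
})

test_that("a triple of mutual duplicates loses exactly two members", {
  set.seed(13)
  n_genes <- 500
  base <- rnorm(n_genes)
  mat <- cbind(s1 = base, s2 = base + rnorm(n_genes, 0, 0.01),
               s3 = base + rnorm(n_genes, 0, 0.01),
               s4 = rnorm(n_genes))
  rownames(mat) <- sprintf("G%03d", 1:n_genes)
  coll <- cohort_collection(list(list(
    expr = expression_dataset(mat, dataset_id = "d1"),
    clinical = clinical_table(data.frame(sample_id = colnames(mat),
                                         dataset_id = "d1",
                                         sample_type = "tumor")))))
  res <- remove_duplicates(coll)
  expect_equal(ncol(res$collection[["d1"]]$expr$exprs), 2)  # s4 + one of s1-s3
  # lexicographically first member survives within a dataset
  expect_true("s1" %in% colnames(res$collection[["d1"]]$expr$exprs))
})

test_that("filter_collection applies sample-type and size rules monotonically", {
  big <- make_cohort("big", n = 60, seed = 1)
  small <- make_cohort("small", n = 40, seed = 2)
  mixed <- make_cohort("mixed", n = 50, seed = 3)
  mixed$clinical$sample_type[1:10] <- "healthy"
  coll <- cohort_collection(list(big, small, mixed))

  kept <- filter_collection(coll, min_samples = 50, tumor_only = FALSE)
  expect_setequal(names(kept), c("big", "mixed"))

  kept2 <- filter_collection(coll, min_samples = 50, tumor_only = TRUE)
  expect_setequal(names(kept2), "big")  # mixed drops to 40 tumor samples
  expect_equal(ncol(filter_collection(coll, tumor_only = TRUE)[["mixed"]]$expr$exprs),
               40)

  # monotone: raising min_samples never retains more datasets
  sizes <- vapply(c(0, 30, 45, 55, 100), function(ms)
    length(suppressWarnings(filter_collection(coll, min_samples = ms))), 0)
  expect_true(all(diff(sizes) <= 0))

  # event threshold
  few_events <- make_cohort("few", n = 50, seed = 4)
  few_events$clinical$vital_status[] <- "living"
  coll2 <- cohort_collection(list(big, few_events))
  expect_setequal(names(filter_collection(coll2, min_events = 5)), "big")
})
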