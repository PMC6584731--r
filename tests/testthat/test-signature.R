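fake_scan <- function(genes, hr, q) {
  data.frame(gene = genes, k = 8, log_hr = log(hr), se = 0.1, hr = hr,
             ci_lo = hr * 0.9, ci_hi = hr * 1.1, p = q / 2, q = q,
             tau2 = 0, cochran_q = 0, stringsAsFactors = FALSE)
}

test_that("discover_signature applies the FDR/HR/concordance rules", {
  a <- fake_scan(c("g1", "g2", "g3", "g4", "g5"),
                 hr = c(1.30, 1.30, 0.80, 1.05, 1.40),
                 q  = c(0.04, 0.04, 0.01, 0.01, 0.20))
  b <- fake_scan(c("g1", "g2", "g3", "g4", "g5"),
                 hr = c(1.20, 0.80, 0.70, 1.30, 1.50),
                 q  = c(0.01, 0.02, 0.02, 0.01, 0.01))
  sig <- discover_signature(list(A = a, B = b))
  # g1 concordant risk; g3 concordant protective; g2 discordant; g4 fails the
  # HR band in A; g5 fails FDR in A
  expect_setequal(sig$genes$gene, c("g1", "g3"))
  expect_equal(sig$genes$direction[sig$genes$gene == "g1"], 1L)
  expect_equal(sig$genes$direction[sig$genes$gene == "g3"], -1L)

  sig2 <- discover_signature(list(A = a, B = b),
                             selection_config(require_concordance = FALSE))
  expect_setequal(sig2$genes$gene, c("g1", "g2", "g3"))

  expect_warning(
    empty <- discover_signature(list(A = fake_scan("g9", 1.0, 0.9),
                                     B = fake_scan("g9", 1.0, 0.9))),
    "empty")
  expect_equal(nrow(empty$genes), 0)
  expect_error(discover_signature(list(A = a)), "two cancer types")
})

test_that("discovery is invariant to gene order and cancer-type order", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:30)
  a <- fake_scan(genes, hr = exp(rnorm(30, 0, 0.3)), q = runif(30, 0, 0.2))
  b <- fake_scan(genes, hr = exp(rnorm(30, 0, 0.3)), q = runif(30, 0, 0.2))
  s1 <- discover_signature(list(A = a, B = b))
  s2 <- discover_signature(list(B = b, A = a[sample(30), ]))
  expect_identical(s1$genes, s2$genes)
})

test_that("the packaged 53-gene signature matches its printed composition", {
  sig <- metagx_signature()
  expect_equal(nrow(sig$genes), 53)
  expect_false(anyDuplicated(sig$genes$gene) > 0)
  expect_true(all(sig$genes$direction %in% c(-1L, 1L)))
  expect_equal(sum(sig$genes$direction == 1), 41)
  expect_equal(sum(sig$genes$direction == -1), 12)
  dir_of <- setNames(sig$genes$direction, sig$genes$gene)
  expect_equal(dir_of[["PLAU"]], 1L)
  expect_equal(dir_of[["DDB2"]], -1L)
  expect_equal(dir_of[["FAM189A2"]], -1L)
  ann <- attr(sig, "annotation")
  expect_equal(ann$entrez_id[ann$symbol == "EGFR"], 1956)
})

test_that("bundled reference gene sets have the printed sizes", {
  expect_equal(length(ovarian_prognostic_genes()), 6)
  expect_true(all(c("PTCH1", "NUAK1") %in% ovarian_prognostic_genes()))
  expect_equal(length(breast_module_prototypes()), 7)
  expect_true(all(c("ESR1", "AURKA", "PLAU") %in% breast_module_prototypes()))
})

test_that("signed_average_score reduces to signed means of standardized values", {
  # rows built so sample s1 has standardized value exactly +1 for every gene
  sig <- gene_signature(c("A", "B"), c(1, -1))
  mat <- rbind(A = c(1, -1, 0), B = c(1, -1, 0))
  colnames(mat) <- c("s1", "s2", "s3")
  ds <- expression_dataset(mat, dataset_id = "toy")
  sc <- signed_average_score(ds, sig)
  expect_equal(unname(sc["s1"]), 0)          # +1 and -1 cancel
  all_pos <- gene_signature(c("A", "B"), c(1, 1))
  sc2 <- signed_average_score(ds, all_pos)
  expect_equal(unname(sc2["s1"]), 1)         # mean of standardized values

  # full published signature: a sample at +1 for every gene scores
  # (n_pos - n_neg) / 53
  full <- metagx_signature()
  mat53 <- matrix(rep(c(1, -1, 0), each = 53), 53, 3,
                  dimnames = list(full$genes$gene, c("s1", "s2", "s3")))
  ds53 <- expression_dataset(mat53, dataset_id = "table1")
  sc53 <- signed_average_score(ds53, full)
  expect_equal(unname(sc53["s1"]), (41 - 12) / 53)
})

test_that("scores are linear in directions and handle missing genes", {
  co <- make_cohort(n_genes = 10, n = 30, seed = 44)
  sig <- gene_signature(sprintf("G%03d", 1:6), c(1, 1, 1, -1, -1, 1))
  flipped <- gene_signature(sig$genes$gene, -sig$genes$direction)
  s1 <- signed_average_score(co$expr, sig)
  s2 <- signed_average_score(co$expr, flipped)
  expect_equal(s2, -s1, tolerance = 1e-12)

  # unmeasured genes drop out of the denominator
  sig_extra <- gene_signature(c(sig$genes$gene, "NOT_MEASURED"),
                              c(sig$genes$direction, 1))
  expect_warning(s3 <- signed_average_score(co$expr, sig_extra),
                 regexp = NA)   # coverage 6/7 > 50%: no warning
  expect_equal(as.vector(s3), as.vector(s1), tolerance = 1e-12)

  mostly_missing <- gene_signature(c("G001", sprintf("X%02d", 1:9)),
                                   rep(1, 10))
  expect_warning(signed_average_score(co$expr, mostly_missing), "coverage")
  none <- gene_signature("ZZZ", 1)
  expect_error(signed_average_score(co$expr, none), "no signature gene")
})

test_that("signature JSON round-trips", {
  sig <- gene_signature(c("TP53", "EGFR"), c(-1, 1), name = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_identical(back$genes, sig$genes)
  expect_identical(back$name, "toy")
})

test_that("random_signature_null is deterministic and uses the add-one rule", {
  cfg <- synthetic_config(n_cancer_types = 1, datasets_per_type = 3,
                          samples_per_dataset = c(80, 80), n_genes = 300,
                          n_shared_prognostic = 10, n_type_specific = 0,
                          effect_log_hr = 0.5, seed = 71)
  sim <- generate_collection(cfg)
  scan <- genomewide_meta(sim$collection, min_datasets = 3)
  planted <- sim$truth$gene[sim$truth$true_log_hr != 0]
  dirs <- ifelse(sim$truth$true_log_hr[match(planted, sim$truth$gene)] > 0, 1, -1)
  sig <- gene_signature(planted, dirs, name = "planted")

  nt1 <- random_signature_null(sim$collection, scan, sig, n_random = 60,
                               seed = 9)
  nt2 <- random_signature_null(sim$collection, scan, sig, n_random = 60,
                               seed = 9)
  expect_identical(nt1$null_distribution, nt2$null_distribution)
  expect_identical(nt1$p, nt2$p)
  # add-one permutation formula
  expect_equal(nt1$p,
               (1 + sum(abs(nt1$null_distribution) >= abs(nt1$observed))) / 61)
  # a strongly planted signature beats random gene sets
  expect_lt(nt1$p, 0.05)
  expect_error(random_signature_null(sim$collection, scan, sig,
                                     n_random = 5, seed = 1, size = 10000),
               "exceeds")
})
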