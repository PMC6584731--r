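small_cfg <- function(...) {
  synthetic_config(n_cancer_types = 2, datasets_per_type = 3,
                   samples_per_dataset = c(60, 90), n_genes = 150,
                   n_shared_prognostic = 5, n_type_specific = 2,
                   n_subtypes = 2, ...)
}

test_that("generation is deterministic and stable under added datasets", {
  s1 <- generate_collection(small_cfg(seed = 5))
  s2 <- generate_collection(small_cfg(seed = 5))
  expect_identical(s1$collection[["synthetic-1_D02"]]$expr$exprs,
                   s2$collection[["synthetic-1_D02"]]$expr$exprs)
  expect_identical(s1$truth, s2$truth)

  # counter-based child seeds: earlier datasets unchanged when more are added
  bigger <- generate_collection(
    synthetic_config(n_cancer_types = 2, datasets_per_type = 4,
                     samples_per_dataset = c(60, 90), n_genes = 150,
                     n_shared_prognostic = 5, n_type_specific = 2,
                     n_subtypes = 2, seed = 5))
  for (id in c("synthetic-1_D01", "synthetic-1_D03"))
    expect_identical(bigger$collection[[id]]$expr$exprs,
                     s1$collection[[id]]$expr$exprs)
})

test_that("planted truth bookkeeping is consistent", {
  sim <- generate_collection(small_cfg(seed = 6))
  tr <- sim$truth
  # per cancer type: exactly shared + type-specific genes carry an effect
  for (ty in unique(tr$cancer_type))
    expect_equal(sum(tr$true_log_hr[tr$cancer_type == ty] != 0), 5 + 2)
  shared_genes <- unique(tr$gene[tr$shared])
  expect_equal(length(shared_genes), 5)
  # shared genes carry the same effect in every cancer type
  for (g in shared_genes) {
    vals <- tr$true_log_hr[tr$gene == g]
    expect_equal(length(unique(vals)), 1)
    expect_equal(abs(vals[1]), 0.35)
  }
  # type-specific genes are planted in exactly one type
  spec <- tr[tr$true_log_hr != 0 & !tr$shared, ]
  expect_true(all(table(spec$gene) == 1))
})

test_that("achieved censoring tracks the target on average", {
  sim <- generate_collection(small_cfg(seed = 7,
                                       censoring_fraction_target = 0.3))
  expect_lt(abs(mean(sim$achieved_censoring) - 0.3), 0.05)
  sim2 <- generate_collection(small_cfg(seed = 8,
                                        censoring_fraction_target = 0.6))
  expect_lt(abs(mean(sim2$achieved_censoring) - 0.6), 0.05)
})

test_that("survival times follow proportional hazards by construction", {
  # doubling the baseline hazard halves the median event time
  base <- synthetic_config(n_cancer_types = 1, datasets_per_type = 4,
                           samples_per_dataset = c(400, 400), n_genes = 100,
                           n_shared_prognostic = 0, n_type_specific = 0,
                           n_subtypes = 1, censoring_fraction_target = 0.02,
                           baseline_hazard = 1 / 1000, seed = 9)
  fast <- base; fast$baseline_hazard <- 2 / 1000
  med <- function(sim) median(unlist(lapply(sim$collection, function(co) {
    ep <- extract_endpoint(co$clinical)
    ep$time[ep$event == 1]
  })))
  m1 <- med(generate_collection(base))
  m2 <- med(generate_collection(fast))
  expect_equal(m2 / m1, 0.5, tolerance = 0.12)
})

test_that("per-dataset Cox intervals cover the planted marginal effect", {
  cfg <- synthetic_config(n_cancer_types = 1, datasets_per_type = 10,
                          samples_per_dataset = c(200, 200), n_genes = 60,
                          n_shared_prognostic = 4, n_type_specific = 0,
                          effect_log_hr = 0.4, between_study_sd = 0,
                          n_subtypes = 1, seed = 10)
  sim <- generate_collection(cfg)
  planted <- unique(sim$truth$gene[sim$truth$true_log_hr != 0])
  covered <- c()
  for (co in sim$collection) {
    ep <- extract_endpoint(co$clinical)
    for (g in planted) {
      x <- co$expr$exprs[g, ep$sample_id]
      x <- (x - mean(x)) / sd(x)
      f <- fit_cox(x, ep$time, ep$event)
      tr <- sim$truth$true_log_hr[sim$truth$gene == g]
      covered <- c(covered, abs(f$coef - tr) < qnorm(0.975) * f$se)
    }
  }
  expect_gt(mean(covered), 0.85)   # nominal 95% minus residual attenuation
})

test_that("multi-probe expansion is recovered by max-IQR collapsing", {
  cfg <- small_cfg(seed = 12, multiprobe_fraction = 0.3)
  sim <- generate_collection(cfg)
  co <- sim$collection[[1]]
  expect_gt(nrow(co$expr$exprs), 150)
  collapsed <- collapse_probes(co$expr)
  expect_equal(nrow(collapsed$exprs), 150)
  # informative probes dominate the chosen set (extra probes are attenuated)
  prov <- attr(collapsed, "provenance")
  multi <- prov$gene[prov$gene %in%
                       co$expr$features$gene_symbol[duplicated(co$expr$features$gene_symbol)]]
  chosen <- prov$probe_id[match(multi, prov$gene)]
  expect_gt(mean(grepl("_p1$", chosen)), 0.8)
})

test_that("injected duplicates are registered and detectable", {
  sim <- generate_collection(small_cfg(seed = 13))
  dup <- inject_duplicates(sim$collection, rate = 0.02, seed = 14)
  expect_gt(nrow(dup$registry), 0)
  res <- remove_duplicates(dup$collection)
  found <- apply(dup$registry, 1, function(r)
    any((res$report$kept_id == r[["source_id"]] &
           res$report$removed_id == r[["duplicate_id"]]) |
          (res$report$kept_id == r[["duplicate_id"]] &
             res$report$removed_id == r[["source_id"]])))
  expect_true(all(found))

  # rate 0 leaves the collection untouched
  dup0 <- inject_duplicates(sim$collection, rate = 0, seed = 14)
  expect_identical(dup0$collection, sim$collection)
  expect_equal(nrow(dup0$registry), 0)
})

test_that("heavily noised copies fall below the correlation threshold", {
  sim <- generate_collection(small_cfg(seed = 15))
  dup <- inject_duplicates(sim$collection, rate = 0.02, seed = 16,
                           noise_sd = 1.5)
  res <- remove_duplicates(dup$collection)
  found <- nrow(res$report) > 0 &&
    any(res$report$removed_id %in% dup$registry$duplicate_id |
          res$report$kept_id %in% dup$registry$duplicate_id)
  expect_false(found)
})
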