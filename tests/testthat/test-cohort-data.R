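test_that("write_dataset / read_dataset round-trips matrices and coded fields", {
  co <- make_cohort(n_genes = 3, n = 4, seed = 5)
  dir <- withr::local_tempdir()
  write_dataset(co$expr, co$clinical, dir)
  back <- read_dataset(file.path(dir, "ds1_expression.tsv"),
                       file.path(dir, "ds1_annotation.tsv"),
                       file.path(dir, "ds1_clinical.csv"),
                       cancer_type = co$expr$cancer_type)
  expect_equal(back$expr$exprs, co$expr$exprs, tolerance = 1e-12)
  expect_identical(back$clinical$vital_status, co$clinical$vital_status)
  expect_identical(back$clinical$sample_id, co$clinical$sample_id)
  expect_equal(back$clinical$days_to_death, co$clinical$days_to_death,
               tolerance = 1e-12)
  expect_identical(back$expr$features$probe_id, co$expr$features$probe_id)
  # second round trip is exact
  dir2 <- withr::local_tempdir()
  write_dataset(back$expr, back$clinical, dir2)
  again <- read_dataset(file.path(dir2, "ds1_expression.tsv"),
                        file.path(dir2, "ds1_annotation.tsv"),
                        file.path(dir2, "ds1_clinical.csv"))
  expect_identical(again$expr$exprs, back$expr$exprs)
})

test_that("unknown clinical codes are coerced to missing with a warning", {
  df <- data.frame(sample_id = c("a", "b"), sample_type = "tumor",
                   days_to_death = c(100, 200),
                   vital_status = c("dead", "living"))
  # the rejected status code then leaves a death time without vital status,
  # which is itself warned about and dropped
  expect_warning(
    expect_warning(cl <- clinical_table(df), "outside the controlled vocabulary"),
    "no vital_status")
  expect_true(is.na(cl$vital_status[1]))
  expect_identical(cl$vital_status[2], "living")
  # the literal code "missing" also maps to NA, silently
  df2 <- data.frame(sample_id = "a", er_status = "missing")
  expect_silent(cl2 <- clinical_table(df2))
  expect_true(is.na(cl2$er_status))
})

test_that("clinical invariants: positive times, status required with time", {
  expect_warning(
    cl <- clinical_table(data.frame(sample_id = c("a", "b"),
                                    days_to_death = c(-5, 10),
                                    vital_status = "deceased")),
    "non-positive")
  expect_true(is.na(cl$days_to_death[1]))
  expect_warning(
    cl2 <- clinical_table(data.frame(sample_id = "a", days_to_death = 100)),
    "no vital_status")
  expect_true(is.na(cl2$days_to_death))
  expect_error(clinical_table(data.frame(sample_id = c("a", "a"))),
               "duplicated")
})

test_that("survival times convert from months and years to days", {
  df <- data.frame(sample_id = "a", days_to_death = 12,
                   vital_status = "deceased")
  expect_equal(clinical_table(df, time_unit = "months")$days_to_death, 365.25)
  expect_equal(clinical_table(df, time_unit = "years")$days_to_death,
               12 * 365.25)
})

test_that("extract_endpoint applies censoring and missingness semantics", {
  cl <- suppressWarnings(clinical_table(data.frame(
    sample_id = c("a", "b", "c", "d"),
    days_to_death = c(400, NA, 250, 90),
    vital_status = c("living", "deceased", "deceased", NA),
    days_to_recurrence = c(200, NA, NA, NA),
    recurrence_status = c("recurred", NA, NA, NA))))
  os <- extract_endpoint(cl, "overall_survival")
  expect_identical(os$sample_id, c("a", "c"))
  expect_equal(os$time, c(400, 250))
  expect_equal(os$event, c(0L, 1L))
  rf <- extract_endpoint(cl, "recurrence_free")
  expect_equal(rf, data.frame(sample_id = "a", time = 200, event = 1L))
  expect_true(all(os$time > 0))
})

test_that("reader rejects malformed headers and mismatched sample ids", {
  dir <- withr::local_tempdir()
  co <- make_cohort(n_genes = 3, n = 3, seed = 2)
  paths <- write_dataset(co$expr, co$clinical, dir)

  bad_expr <- file.path(dir, "bad_expr.tsv")
  tab <- read.delim(paths[["expression"]], check.names = FALSE)
  names(tab)[1] <- "gene"
  write.table(tab, bad_expr, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_dataset(bad_expr, paths[["annotation"]],
                            paths[["clinical"]]), "feature_id")

  bad_clin <- file.path(dir, "bad_clin.csv")
  cl <- read.csv(paths[["clinical"]])
  cl$sample_id[1] <- "stranger"
  write.csv(cl, bad_clin, row.names = FALSE)
  expect_error(read_dataset(paths[["expression"]], paths[["annotation"]],
                            bad_clin), "orphans.*stranger|stranger")
})

test_that("cohort_collection enforces sample reconciliation and groups types", {
  co1 <- make_cohort("d1", "synthetic-1", seed = 1)
  co2 <- make_cohort("d2", "synthetic-2", seed = 2)
  coll <- cohort_collection(list(co1, co2))
  expect_named(attr(coll, "grouping"), c("synthetic-1", "synthetic-2"))
  broken <- co1
  broken$clinical <- broken$clinical[-1, ]
  expect_error(cohort_collection(list(broken)), "disagree")
})
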