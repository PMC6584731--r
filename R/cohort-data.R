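# Data model for multi-cancer, multi-dataset expression + clinical cohorts.
#
# A cohort is a pair (expression_dataset, clinical_table); a cohort_collection
# groups cohorts by cancer type. Clinical tables follow a closed controlled
# vocabulary; unknown codes are coerced to missing with a warning rather than
# rejected, mirroring tolerant semi-automatic curation of heterogeneous
# public cohorts.

CLINICAL_COLUMNS <- c(
  "sample_id", "dataset_id", "sample_type", "age_at_diagnosis", "grade",
  "stage", "er_status", "pgr_status", "her2_status", "subtype",
  "days_to_death", "vital_status", "days_to_recurrence", "recurrence_status",
  "treatment"
)

CLINICAL_VOCABULARY <- list(
  sample_type       = c("tumor", "healthy"),
  er_status         = c("positive", "negative"),
  pgr_status        = c("positive", "negative"),
  her2_status       = c("positive", "negative"),
  vital_status      = c("deceased", "living"),
  recurrence_status = c("recurred", "norecurrence"),
  treatment         = c("yes", "no")
)

DAYS_PER_UNIT <- c(days = 1, months = 365.25 / 12, years = 365.25)

#' Construct an expression dataset
#'
#' A single cohort's log-scale expression matrix (features x samples) together
#' with its feature annotation (probe to gene symbol / Entrez id mapping).
#'
#' @param exprs numeric matrix, features in rows, samples in columns; row
#'   names are probe/feature ids, column names are sample ids. `NA` marks
#'   missing values; all other entries must be finite.
#' @param features data frame with columns `probe_id`, `gene_symbol`,
#'   `entrez_id` (symbol or Entrez id may be `NA`; a feature is gene-mappable
#'   when at least one is present). Defaults to an identity mapping from the
#'   matrix row names.
#' @param dataset_id,cancer_type identifiers; `cancer_type` is typically one
#'   of `"breast"`, `"ovarian"`, `"pancreas"` or `"synthetic-<k>"`.
#' @return an object of class `"expression_dataset"`.
#' @export
expression_dataset <- function(exprs, features = NULL, dataset_id = "dataset",
                               cancer_type = "synthetic-1") {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("expression matrix must have feature row names and sample column names")
  if (anyDuplicated(rownames(exprs)))
    stop("duplicated feature ids in expression matrix")
  if (anyDuplicated(colnames(exprs)))
    stop("duplicated sample ids in expression matrix")
  if (any(is.infinite(exprs)))
    stop("expression values must be finite or NA")
  if (is.null(features)) {
    features <- data.frame(
      probe_id = rownames(exprs), gene_symbol = rownames(exprs),
      entrez_id = NA_integer_, stringsAsFactors = FALSE
    )
  }
  need <- c("probe_id", "gene_symbol", "entrez_id")
  if (!all(need %in% names(features)))
    stop("feature annotation must have columns probe_id, gene_symbol, entrez_id")
  features <- features[need]
  if (anyDuplicated(features$probe_id))
    stop("duplicated probe_id in feature annotation")
  if (!setequal(features$probe_id, rownames(exprs)))
    stop("feature annotation probe_id set must match expression row names")
  features <- features[match(rownames(exprs), features$probe_id), ]
  rownames(features) <- NULL
  structure(
    list(dataset_id = dataset_id, cancer_type = cancer_type,
         exprs = exprs, features = features),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s (%s): %d features x %d samples\n",
              x$dataset_id, x$cancer_type, nrow(x$exprs), ncol(x$exprs)))
  n_mapped <- sum(!is.na(x$features$gene_symbol) | !is.na(x$features$entrez_id))
  cat(sprintf("  gene-mappable features: %d; missing values: %d\n",
              n_mapped, sum(is.na(x$exprs))))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$exprs)

#' Validate and standardize a clinical table
#'
#' Coerces a per-sample clinical data frame to the controlled vocabulary.
#' Unknown codes in vocabulary columns (including the literal code
#' `"missing"`) become `NA`; a single warning reports how many values were
#' coerced. Survival times are converted to days according to `time_unit`.
#'
#' @param df data frame with (a subset of) the standard clinical columns; at
#'   minimum `sample_id`. Missing columns are added as all-`NA`.
#' @param time_unit unit of `days_to_death` / `days_to_recurrence` in `df`;
#'   converted to days.
#' @return data frame of class `"clinical_table"` with the standard columns.
#' @export
clinical_table <- function(df, time_unit = c("days", "months", "years")) {
  time_unit <- match.arg(time_unit)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table must have a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in clinical table")
  extra <- setdiff(names(df), CLINICAL_COLUMNS)
  if (length(extra))
    warning("ignoring unknown clinical columns: ", paste(extra, collapse = ", "))
  for (col in setdiff(CLINICAL_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[CLINICAL_COLUMNS]

  n_coerced <- 0L
  for (col in names(CLINICAL_VOCABULARY)) {
    v <- as.character(df[[col]])
    bad <- !is.na(v) & !(v %in% CLINICAL_VOCABULARY[[col]]) & v != "missing"
    n_coerced <- n_coerced + sum(bad)
    v[bad | v == "missing"] <- NA
    df[[col]] <- v
  }
  if (n_coerced > 0)
    warning(sprintf("%d clinical values outside the controlled vocabulary coerced to missing",
                    n_coerced))

  df$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
  grade <- suppressWarnings(as.integer(df$grade))
  grade[!is.na(grade) & !(grade %in% 1:4)] <- NA
  df$grade <- grade
  df$stage <- as.character(df$stage)
  df$subtype <- as.character(df$subtype)
  df$dataset_id <- as.character(df$dataset_id)

  unit <- DAYS_PER_UNIT[[time_unit]]
  for (col in c("days_to_death", "days_to_recurrence")) {
    tm <- as.numeric(df[[col]]) * unit
    bad <- !is.na(tm) & tm <= 0
    if (any(bad)) {
      warning(sprintf("%d non-positive %s values coerced to missing", sum(bad), col))
      tm[bad] <- NA
    }
    df[[col]] <- tm
  }
  # a recorded death/follow-up time without vital status is unusable
  orphan <- !is.na(df$days_to_death) & is.na(df$vital_status)
  if (any(orphan)) {
    warning(sprintf("%d samples have days_to_death but no vital_status; time dropped",
                    sum(orphan)))
    df$days_to_death[orphan] <- NA
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Group cohorts into a collection
#'
#' @param cohorts list of `list(expr = expression_dataset, clinical =
#'   clinical_table)` pairs. Expression and clinical sample ids must coincide
#'   exactly within each cohort.
#' @return object of class `"cohort_collection"`: a named list of cohorts with
#'   a `cancer_type` grouping attribute.
#' @export
cohort_collection <- function(cohorts) {
  ids <- vapply(cohorts, function(co) co$expr$dataset_id, "")
  if (anyDuplicated(ids)) stop("duplicated dataset_id in collection")
  cohorts <- lapply(cohorts, function(co) {
    eid <- colnames(co$expr$exprs)
    cid <- co$clinical$sample_id
    if (!setequal(eid, cid)) {
      orphans <- c(setdiff(eid, cid), setdiff(cid, eid))
      stop(sprintf("sample ids disagree between expression and clinical in %s: %s",
                   co$expr$dataset_id, paste(head(orphans, 10), collapse = ", ")))
    }
    # keep clinical rows in matrix column order
    co$clinical <- co$clinical[match(eid, cid), ]
    rownames(co$clinical) <- NULL
    co
  })
  names(cohorts) <- ids
  types <- vapply(cohorts, function(co) co$expr$cancer_type, "")
  structure(cohorts, class = "cohort_collection",
            grouping = split(ids, types))
}

#' @export
print.cohort_collection <- function(x, ...) {
  cat(sprintf("<cohort_collection> %d datasets, %d cancer types\n",
              length(x), length(attr(x, "grouping"))))
  for (type in names(attr(x, "grouping"))) {
    ids <- attr(x, "grouping")[[type]]
    n <- sum(vapply(x[ids], function(co) ncol(co$expr$exprs), 0))
    cat(sprintf("  %s: %d datasets, %d samples\n", type, length(ids), n))
  }
  invisible(x)
}

#' @export
summary.cohort_collection <- function(object, ...) {
  rows <- lapply(object, function(co) {
    os <- extract_endpoint(co$clinical, "overall_survival")
    data.frame(dataset_id = co$expr$dataset_id,
               cancer_type = co$expr$cancer_type,
               n_features = nrow(co$expr$exprs),
               n_samples = ncol(co$expr$exprs),
               n_tumor = sum(co$clinical$sample_type %in% "tumor"),
               n_os = nrow(os), n_events = sum(os$event),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read one cohort from disk
#'
#' Reads the three on-disk files of a cohort: a tab-separated expression
#' matrix (first column `feature_id`, remaining columns samples, `NA` for
#' missing), a tab-separated feature annotation (`probe_id`, `gene_symbol`,
#' `entrez_id`) and a comma-separated clinical table with the standard
#' columns.
#'
#' @param expression_path,annotation_path,clinical_path file paths.
#' @param dataset_id,cancer_type identifiers for the resulting dataset;
#'   `dataset_id` defaults to the clinical table's `dataset_id` column when
#'   present.
#' @param time_unit unit of survival times in the clinical file.
#' @return `list(expr = expression_dataset, clinical = clinical_table)`.
#' @export
read_dataset <- function(expression_path, annotation_path, clinical_path,
                         dataset_id = NULL, cancer_type = "synthetic-1",
                         time_unit = "days") {
  for (p in c(expression_path, annotation_path, clinical_path))
    if (!file.exists(p)) stop("file not found: ", p)

  em <- read.delim(expression_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(em)[1] != "feature_id")
    stop("malformed expression header: first column must be 'feature_id', got '",
         names(em)[1], "'")
  mat <- as.matrix(em[, -1, drop = FALSE])
  rownames(mat) <- em$feature_id
  storage.mode(mat) <- "double"

  ann <- read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "entrez_id")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("malformed annotation header: missing column(s) ",
         paste(miss, collapse = ", "))
  ann$entrez_id <- suppressWarnings(as.integer(ann$entrez_id))

  cl <- read.csv(clinical_path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(cl))
    stop("malformed clinical header: missing column 'sample_id'")
  cl <- clinical_table(cl, time_unit = time_unit)

  e_ids <- colnames(mat)
  c_ids <- cl$sample_id
  if (!setequal(e_ids, c_ids)) {
    orphans <- c(setdiff(e_ids, c_ids), setdiff(c_ids, e_ids))
    stop("expression/clinical sample id mismatch; orphans: ",
         paste(head(orphans, 20), collapse = ", "))
  }
  cl <- cl[match(e_ids, c_ids), ]
  rownames(cl) <- NULL
  if (is.null(dataset_id)) {
    dataset_id <- if (!all(is.na(cl$dataset_id))) cl$dataset_id[1] else "dataset"
  }
  expr <- expression_dataset(mat, ann, dataset_id = dataset_id,
                             cancer_type = cancer_type)
  list(expr = expr, clinical = cl)
}

#' Write one cohort to disk
#'
#' Counterpart of [read_dataset()]; values round-trip to at least 15
#' significant digits.
#'
#' @param expr an `expression_dataset`.
#' @param clinical its `clinical_table`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix; defaults to the dataset id.
#' @return invisibly, a named character vector of the three paths written.
#' @export
write_dataset <- function(expr, clinical, dir, prefix = expr$dataset_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, paste0(prefix, "_expression.tsv")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    clinical   = file.path(dir, paste0(prefix, "_clinical.csv"))
  )
  em <- data.frame(feature_id = rownames(expr$exprs),
                   format(expr$exprs, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(em, paths[["expression"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(expr$features, paths[["annotation"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cl <- as.data.frame(clinical)
  for (col in c("days_to_death", "days_to_recurrence", "age_at_diagnosis"))
    cl[[col]] <- format(cl[[col]], digits = 15, trim = TRUE, scientific = FALSE)
  write.csv(cl, paths[["clinical"]], row.names = FALSE, quote = FALSE, na = "NA")
  invisible(paths)
}

#' Extract a survival endpoint from a clinical table
#'
#' For overall survival, the event indicator is 1 iff `vital_status` is
#' `"deceased"`; `days_to_death` carries the follow-up time for both deceased
#' and living (censored) samples. Samples lacking either time or status are
#' excluded.
#'
#' @param clinical a `clinical_table`.
#' @param endpoint `"overall_survival"` or `"recurrence_free"`.
#' @return data frame with columns `sample_id`, `time` (days, > 0), `event`
#'   (0/1); possibly zero rows.
#' @export
extract_endpoint <- function(clinical,
                             endpoint = c("overall_survival", "recurrence_free")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "overall_survival") {
    time <- clinical$days_to_death
    event <- as.integer(clinical$vital_status == "deceased")
  } else {
    time <- clinical$days_to_recurrence
    event <- as.integer(clinical$recurrence_status == "recurred")
  }
  keep <- !is.na(time) & !is.na(event) & time > 0
  data.frame(sample_id = clinical$sample_id[keep], time = time[keep],
             event = event[keep], stringsAsFactors = FALSE)
}
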