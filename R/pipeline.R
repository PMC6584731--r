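# Orchestration of the analysis stages behind a single declarative config:
# simulate -> curate -> scan -> discover -> score -> validate -> nulltest,
# with per-gene forest analyses via "prognose". Every stage writes its
# artifacts plus a manifest (seed, config hash, package version, input and
# output checksums) so that a rerun with the same config and seed is
# byte-reproducible.

#' Write / read a whole collection in the on-disk cohort formats
#'
#' Each cohort is written via [write_dataset()]; an `index.json` records
#' dataset ids, cancer types and file names.
#'
#' @param collection a `cohort_collection`.
#' @param dir directory.
#' @return `write_collection`: invisibly, the index path;
#'   `read_collection`: a `cohort_collection`.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- lapply(collection, function(co) {
    write_dataset(co$expr, co$clinical, dir)
    list(dataset_id = co$expr$dataset_id, cancer_type = co$expr$cancer_type)
  })
  path <- file.path(dir, "index.json")
  jsonlite::write_json(unname(index), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  index <- jsonlite::fromJSON(file.path(dir, "index.json"),
                              simplifyDataFrame = FALSE)
  cohorts <- lapply(index, function(e) {
    read_dataset(
      file.path(dir, paste0(e$dataset_id, "_expression.tsv")),
      file.path(dir, paste0(e$dataset_id, "_annotation.tsv")),
      file.path(dir, paste0(e$dataset_id, "_clinical.csv")),
      dataset_id = e$dataset_id, cancer_type = e$cancer_type)
  })
  cohort_collection(cohorts)
}

default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "metasig_run",
    simulate = list(),
    curate = list(collapse = TRUE, rho_threshold = 0.98, min_samples = 30,
                  min_events = 10, tumor_only = TRUE),
    scan = list(endpoint = "overall_survival", min_datasets = 6,
                model = "random", gene_universe = "threshold"),
    prognose = list(genes = list()),
    discover = list(fdr_max = 0.05, hr_upper = 1.125, hr_lower = 0.875,
                    require_concordance = TRUE,
                    training_cancer_types = NULL, holdout_datasets = list()),
    score = list(),
    validate = list(strata = "subtype"),
    nulltest = list(n_random = 1000, size = NULL)
  )
}

load_pipeline_config <- function(config) {
  user <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
  cfg <- default_pipeline_config()
  for (key in names(user)) {
    if (is.list(user[[key]]) && is.list(cfg[[key]]))
      cfg[[key]] <- utils::modifyList(cfg[[key]], user[[key]])
    else cfg[[key]] <- user[[key]]
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, command, cfg, inputs, outputs) {
  manifest <- list(
    command = command, seed = cfg$seed, config_hash = config_hash(cfg),
    package_version = as.character(packageVersion("metasig")),
    r_version = R.version.string,
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  path <- file.path(out_dir, sprintf("manifest_%s.json", command))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE)
  path
}

# Training collection = curated minus holdouts, restricted to the training
# cancer types when given.
training_split <- function(collection, cfg) {
  holdout <- unlist(cfg$discover$holdout_datasets)
  train_ids <- setdiff(names(collection), holdout)
  types <- cfg$discover$training_cancer_types
  if (!is.null(types)) {
    keep <- vapply(collection[train_ids],
                   function(co) co$expr$cancer_type %in% types, TRUE)
    train_ids <- train_ids[keep]
  }
  if (length(train_ids) == 0)
    stop("no training datasets left after applying holdouts/cancer types")
  list(train = cohort_collection(collection[train_ids]),
       holdout = if (length(holdout))
         cohort_collection(collection[intersect(holdout, names(collection))])
       else NULL)
}

scan_by_type <- function(collection, scan_cfg, min_override = NULL) {
  grouping <- attr(collection, "grouping")
  out <- list()
  for (type in names(grouping)) {
    md <- if (!is.null(min_override)) min_override else
      min(scan_cfg$min_datasets, length(grouping[[type]]))
    out[[type]] <- genomewide_meta(
      collection, endpoint = scan_cfg$endpoint, min_datasets = md,
      model = scan_cfg$model, gene_universe = scan_cfg$gene_universe,
      cancer_type = type)
  }
  out
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` writes a synthetic collection plus ground truth;
#' `"curate"` applies probe collapsing, duplicate removal and cohort filters;
#' `"scan"` runs the genome-wide meta-analysis per cancer type; `"prognose"`
#' writes per-gene forest tables (per-dataset + pooled estimates) for a
#' supplied gene list; `"discover"` selects the cross-cancer signature from
#' the training scans; `"score"` writes per-sample signature scores;
#' `"validate"` evaluates the signature on the holdout cohorts per subtype;
#' `"nulltest"` runs the random-signature permutation null on the holdouts.
#' Each stage reads its inputs from `out_dir` (as written by earlier stages)
#' and writes a manifest.
#'
#' @param command one of the stage names above, or `"all"` to run the full
#'   chain.
#' @param config path to a YAML config file, or an equivalent nested list.
#'   Unspecified entries fall back to package defaults.
#' @return invisibly, a character vector of the artifact paths written.
#' @export
run_pipeline <- function(command = c("all", "simulate", "curate", "scan",
                                     "prognose", "discover", "score",
                                     "validate", "nulltest"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- load_pipeline_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (command == "all") {
    paths <- character()
    for (cmd in c("simulate", "curate", "scan", "discover", "score",
                  "validate", "nulltest"))
      paths <- c(paths, run_pipeline(cmd, cfg))
    return(invisible(paths))
  }

  raw_dir <- file.path(out_dir, "data", "raw")
  cur_dir <- file.path(out_dir, "data", "curated")
  paths <- character()

  if (command == "simulate") {
    sim_cfg <- do.call(synthetic_config,
                       c(cfg$simulate, list(seed = cfg$seed)))
    sim <- generate_collection(sim_cfg)
    write_collection(sim$collection, raw_dir)
    truth_path <- file.path(out_dir, "truth.tsv")
    write_truth(sim$truth, truth_path)
    paths <- c(list.files(raw_dir, full.names = TRUE), truth_path)
    message(sprintf("simulate: %d datasets written to %s",
                    length(sim$collection), raw_dir))
  } else if (command == "curate") {
    collection <- read_collection(raw_dir)
    if (isTRUE(cfg$curate$collapse))
      collection <- cohort_collection(lapply(collection, function(co)
        list(expr = collapse_probes(co$expr), clinical = co$clinical)))
    dedup <- remove_duplicates(collection,
                               rho_threshold = cfg$curate$rho_threshold)
    rep_path <- file.path(out_dir, "duplicate_report.tsv")
    write_duplicate_report(dedup$report, rep_path)
    curated <- filter_collection(dedup$collection,
                                 min_samples = cfg$curate$min_samples,
                                 min_events = cfg$curate$min_events,
                                 tumor_only = cfg$curate$tumor_only)
    write_collection(curated, cur_dir)
    paths <- c(list.files(cur_dir, full.names = TRUE), rep_path)
    message(sprintf("curate: %d datasets kept, %d duplicate pairs flagged",
                    length(curated), nrow(dedup$report)))
  } else if (command == "scan") {
    split <- training_split(read_collection(cur_dir), cfg)
    scans <- scan_by_type(split$train, cfg$scan)
    for (type in names(scans)) {
      p <- file.path(out_dir, sprintf("scan_%s.tsv", type))
      write_meta_scan(scans[[type]], p)
      paths <- c(paths, p)
    }
    message(sprintf("scan: %d cancer types scanned", length(scans)))
  } else if (command == "prognose") {
    genes <- unlist(cfg$prognose$genes)
    if (length(genes) == 0)
      stop("prognose requires a non-empty prognose$genes list")
    collection <- read_collection(cur_dir)
    rows <- list()
    for (co in collection) {
      sc <- scan_dataset(co, endpoint = cfg$scan$endpoint, genes = genes)
      if (!is.null(sc)) rows[[co$expr$dataset_id]] <-
        cbind(dataset_id = co$expr$dataset_id, sc)
    }
    long <- do.call(rbind, c(rows, make.row.names = FALSE))
    pooled <- lapply(split(long, long$gene), function(d) {
      m <- combine_estimates(d$log_hr, d$se, model = cfg$scan$model)
      data.frame(dataset_id = "POOLED", gene = d$gene[1],
                 log_hr = m$pooled_log_hr, se = m$pooled_se,
                 n = sum(d$n), n_events = sum(d$n_events))
    })
    long <- rbind(long, do.call(rbind, c(pooled, make.row.names = FALSE)))
    p <- file.path(out_dir, "prognosis_genes.tsv")
    write.table(long, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- p
    message(sprintf("prognose: %d genes analysed", length(unique(long$gene))))
  } else if (command == "discover") {
    split <- training_split(read_collection(cur_dir), cfg)
    types <- names(attr(split$train, "grouping"))
    if (length(types) < 2)
      stop("discover requires at least two training cancer types")
    scans <- list()
    for (type in types) {
      p <- file.path(out_dir, sprintf("scan_%s.tsv", type))
      scans[[type]] <- if (file.exists(p))
        read.delim(p, stringsAsFactors = FALSE)
      else scan_by_type(cohort_collection(
        split$train[attr(split$train, "grouping")[[type]]]), cfg$scan)[[type]]
    }
    sel <- selection_config(fdr_max = cfg$discover$fdr_max,
                            hr_upper = cfg$discover$hr_upper,
                            hr_lower = cfg$discover$hr_lower,
                            require_concordance = cfg$discover$require_concordance,
                            holdout_dataset_ids = unlist(cfg$discover$holdout_datasets))
    sig <- discover_signature(scans, sel, name = "discovered")
    p <- file.path(out_dir, "signature.json")
    write_signature(sig, p)
    paths <- p
    message(sprintf("discover: %d genes selected", nrow(sig$genes)))
  } else if (command == "score") {
    collection <- read_collection(cur_dir)
    sig <- read_signature(file.path(out_dir, "signature.json"))
    rows <- lapply(collection, function(co) {
      sc <- suppressWarnings(signed_average_score(co$expr, sig))
      data.frame(dataset_id = co$expr$dataset_id, sample_id = names(sc),
                 score = unname(sc), stringsAsFactors = FALSE)
    })
    p <- file.path(out_dir, "scores.tsv")
    write.table(do.call(rbind, c(rows, make.row.names = FALSE)), p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- p
    message("score: scores written")
  } else if (command == "validate") {
    split <- training_split(read_collection(cur_dir), cfg)
    target <- if (!is.null(split$holdout)) split$holdout else split$train
    sig <- read_signature(file.path(out_dir, "signature.json"))
    ev <- evaluate_signature(target, sig, strata = cfg$validate$strata,
                             endpoint = cfg$scan$endpoint,
                             model = cfg$scan$model)
    p <- file.path(out_dir, "evaluation.tsv")
    write_evaluation(ev, p)
    paths <- p
    message(sprintf("validate: %d strata evaluated", nrow(ev)))
  } else if (command == "nulltest") {
    split <- training_split(read_collection(cur_dir), cfg)
    target <- if (!is.null(split$holdout)) split$holdout else split$train
    sig <- read_signature(file.path(out_dir, "signature.json"))
    training_meta <- do.call(rbind, lapply(
      scan_by_type(split$train, cfg$scan),
      function(s) as.data.frame(s)[c("gene", "log_hr")]))
    size <- if (!is.null(cfg$nulltest$size)) cfg$nulltest$size
            else nrow(sig$genes)
    nt <- random_signature_null(target, training_meta, sig,
                                n_random = cfg$nulltest$n_random,
                                seed = cfg$seed, size = size)
    p <- file.path(out_dir, "null_report.tsv")
    write_null_report(nt, p)
    paths <- p
    message(sprintf("nulltest: p = %.4g", nt$p))
  }

  write_manifest(out_dir, command, cfg,
                 inputs = if (command %in% c("simulate")) character()
                          else list.files(file.path(out_dir, "data"),
                                          recursive = TRUE, full.names = TRUE),
                 outputs = paths)
  invisible(paths)
}
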