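# Synthetic multi-cancer, multi-dataset cohorts with known planted truth.
# Expression is standard normal per gene plus dataset-specific per-gene
# location and scale shifts (platform effects); survival follows a
# proportional-hazards model with an exponential baseline and administrative
# uniform censoring calibrated to a target fraction.
#
# Planted prognostic genes are organized into co-expressed "programs": each
# program has a latent per-sample risk factor U ~ N(0,1) that drives the
# hazard, and its member genes read it out with loading sqrt(rho_prog)
# (signs vary by gene). The program coefficient is chosen so that each
# member gene's *marginal* single-gene log hazard ratio per standardized
# expression unit equals the planted effect - the quantity a per-gene scan
# estimates. (Planting many genes with independent additive effects instead
# would build up an omitted-covariate frailty that attenuates every marginal
# estimate far below its nominal value, making the planted truth
# unrecoverable by construction.) One program is shared by all cancer types;
# each type has one type-specific program.

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe the study conditions the package is validated under:
#' three cancer types of ten cohorts each (roughly 120-180 samples per
#' cohort), 2000 genes of which 25 carry a shared prognostic effect of
#' magnitude 0.35 on the log-hazard-per-standardized-unit scale and 10 per
#' type carry a type-specific effect, mild between-study heterogeneity
#' (s.d. 0.05), an exponential baseline hazard of 1/1000 per day and ~20%
#' administrative censoring.
#'
#' @param n_cancer_types,datasets_per_type cohort layout.
#' @param samples_per_dataset inclusive integer range (length 2) of samples
#'   per cohort.
#' @param n_genes genes per cohort (before multi-probe expansion).
#' @param n_shared_prognostic genes planted with the same effect (same sign
#'   and magnitude) in every cancer type.
#' @param n_type_specific genes per cancer type planted in that type only.
#' @param effect_log_hr magnitude of planted effects: the marginal
#'   (single-gene) Cox log hazard ratio per standardized expression unit.
#' @param between_study_sd s.d. of the per-dataset jitter on planted effects.
#' @param program_correlation squared loading of planted genes on their
#'   program's latent risk factor (pairwise correlation of program members).
#' @param baseline_hazard exponential baseline hazard rate, per day.
#' @param censoring_fraction_target target fraction of censored samples.
#' @param duplicate_rate fraction of samples cloned across cohorts of a type
#'   by [inject_duplicates()] when `generate_collection` is asked to.
#' @param multiprobe_fraction fraction of genes measured by 2-3 probes (one
#'   informative, the rest attenuated noisier copies).
#' @param n_subtypes number of molecular subtype labels, driven by a latent
#'   gene block disjoint from the prognostic genes.
#' @param seed master seed; each dataset derives a child seed from it by a
#'   counter scheme, so adding cohorts never perturbs earlier ones.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_cancer_types = 3, datasets_per_type = 10,
                             samples_per_dataset = c(120, 180),
                             n_genes = 2000, n_shared_prognostic = 25,
                             n_type_specific = 10, effect_log_hr = 0.35,
                             between_study_sd = 0.05,
                             program_correlation = 0.8,
                             baseline_hazard = 1 / 1000,
                             censoring_fraction_target = 0.2,
                             duplicate_rate = 0, multiprobe_fraction = 0,
                             n_subtypes = 3, seed = 42) {
  cfg <- list(n_cancer_types = n_cancer_types,
              datasets_per_type = datasets_per_type,
              samples_per_dataset = rep_len(samples_per_dataset, 2),
              n_genes = n_genes, n_shared_prognostic = n_shared_prognostic,
              n_type_specific = n_type_specific, effect_log_hr = effect_log_hr,
              between_study_sd = between_study_sd,
              program_correlation = program_correlation,
              baseline_hazard = baseline_hazard,
              censoring_fraction_target = censoring_fraction_target,
              duplicate_rate = duplicate_rate,
              multiprobe_fraction = multiprobe_fraction,
              n_subtypes = n_subtypes, seed = seed)
  stopifnot(all(unlist(cfg[c("n_cancer_types", "datasets_per_type", "n_genes",
                             "n_shared_prognostic", "n_type_specific",
                             "n_subtypes")]) >= 0),
            cfg$censoring_fraction_target > 0,
            cfg$censoring_fraction_target < 1,
            cfg$program_correlation > 0, cfg$program_correlation < 1,
            cfg$n_shared_prognostic +
              cfg$n_type_specific * cfg$n_cancer_types +
              20 * cfg$n_subtypes <= cfg$n_genes)
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic child seed for dataset counter i (kept below 2^31).
child_seed <- function(seed, i) (as.double(seed) + 1000003 * i) %% 2147483647

# Administrative censoring window giving the target censored fraction for
# exponential event times with per-sample rates `lambda`:
# P(censored) = mean over samples of (1 - exp(-lambda*cmax)) / (lambda*cmax).
calibrate_censoring_window <- function(lambda, target) {
  cens_frac <- function(cmax) mean((1 - exp(-lambda * cmax)) / (lambda * cmax))
  lo <- 1e-6 / mean(lambda); hi <- 1e6 / mean(lambda)
  if (cens_frac(lo) < target) return(lo)
  uniroot(function(cm) cens_frac(cm) - target, c(lo, hi), tol = 1e-8)$root
}

#' Generate a synthetic multi-cancer cohort collection with planted truth
#'
#' @param config a [synthetic_config()].
#' @return list with `collection` (a `cohort_collection`), `truth` (data
#'   frame `gene`, `cancer_type`, `true_log_hr`, `shared`, `subtype_assoc`),
#'   `achieved_censoring` (per dataset) and, when `duplicate_rate > 0`, the
#'   duplicate `registry` of [inject_duplicates()].
#' @export
generate_collection <- function(config = synthetic_config()) {
  cfg <- config
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  types <- paste0("synthetic-", seq_len(cfg$n_cancer_types))

  # planted truth, drawn from the master seed
  set.seed(child_seed(cfg$seed, 0))
  shared_idx <- seq_len(cfg$n_shared_prognostic)
  shared_sign <- sample(c(-1, 1), cfg$n_shared_prognostic, replace = TRUE)
  spec_idx <- lapply(seq_len(cfg$n_cancer_types), function(t)
    cfg$n_shared_prognostic + (t - 1) * cfg$n_type_specific +
      seq_len(cfg$n_type_specific))
  spec_sign <- lapply(seq_len(cfg$n_cancer_types), function(t)
    sample(c(-1, 1), cfg$n_type_specific, replace = TRUE))
  sub_base <- cfg$n_shared_prognostic + cfg$n_cancer_types * cfg$n_type_specific
  sub_idx <- lapply(seq_len(cfg$n_subtypes), function(s)
    sub_base + (s - 1) * 20 + seq_len(20))

  beta <- matrix(0, cfg$n_genes, cfg$n_cancer_types,
                 dimnames = list(genes, types))
  beta[shared_idx, ] <- shared_sign * cfg$effect_log_hr
  for (t in seq_len(cfg$n_cancer_types))
    beta[spec_idx[[t]], t] <- spec_sign[[t]] * cfg$effect_log_hr

  truth <- do.call(rbind, lapply(seq_len(cfg$n_cancer_types), function(t)
    data.frame(gene = genes, cancer_type = types[t], true_log_hr = beta[, t],
               shared = seq_len(cfg$n_genes) %in% shared_idx &
                 beta[, t] != 0,
               subtype_assoc = seq_len(cfg$n_genes) %in% unlist(sub_idx),
               stringsAsFactors = FALSE)))
  rownames(truth) <- NULL

  cohorts <- list()
  achieved <- c()
  counter <- 0L
  for (t in seq_len(cfg$n_cancer_types)) {
    for (j in seq_len(cfg$datasets_per_type)) {
      counter <- counter + 1L
      set.seed(child_seed(cfg$seed, counter))
      ds_id <- sprintf("%s_D%02d", types[t], j)
      rng <- cfg$samples_per_dataset
      n_s <- rng[1] + sample.int(rng[2] - rng[1] + 1L, 1) - 1L
      sample_ids <- sprintf("%s_S%03d", ds_id, seq_len(n_s))

      z <- matrix(rnorm(cfg$n_genes * n_s), cfg$n_genes, n_s,
                  dimnames = list(genes, sample_ids))
      subtype <- sample.int(cfg$n_subtypes, n_s, replace = TRUE)
      for (s in seq_len(cfg$n_subtypes))
        z[sub_idx[[s]], subtype == s] <- z[sub_idx[[s]], subtype == s] + 1

      # planted programs: shared across types + this type's specific one.
      # each program member reads the latent risk factor u with loading `a`;
      # the program's hazard coefficient effect/a makes the marginal
      # single-gene log HR per standardized unit equal the planted effect
      a <- sqrt(cfg$program_correlation)
      b <- sqrt(1 - cfg$program_correlation)
      programs <- list(list(idx = shared_idx, sign = shared_sign),
                       list(idx = spec_idx[[t]], sign = spec_sign[[t]]))
      eta <- rep(0, n_s)
      for (pr in programs) {
        if (length(pr$idx) == 0) next
        u <- rnorm(n_s)
        loading <- matrix(a * u, length(pr$idx), n_s, byrow = TRUE)
        z[pr$idx, ] <- pr$sign * (loading + b * z[pr$idx, , drop = FALSE])
        effect_ds <- cfg$effect_log_hr + rnorm(1, 0, cfg$between_study_sd)
        eta <- eta + (effect_ds / a) * u
      }
      lambda <- cfg$baseline_hazard * exp(eta)
      event_time <- rexp(n_s, rate = lambda)
      cmax <- calibrate_censoring_window(lambda, cfg$censoring_fraction_target)
      expected_cens <- mean((1 - exp(-lambda * cmax)) / (lambda * cmax))
      if (abs(expected_cens - cfg$censoring_fraction_target) > 0.05)
        warning(sprintf(
          "%s: censoring target %.2f infeasible, expected fraction %.2f",
          ds_id, cfg$censoring_fraction_target, expected_cens))
      cens_time <- runif(n_s, 0, cmax)
      time <- pmax(pmin(event_time, cens_time), 1e-3)
      event <- as.integer(event_time <= cens_time)
      achieved[ds_id] <- 1 - mean(event)

      loc <- rnorm(cfg$n_genes)
      scl <- exp(rnorm(cfg$n_genes, 0, 0.2))
      x <- loc + scl * z

      # optional multi-probe expansion: the informative probe carries the
      # full signal; extra probes are attenuated copies with added noise
      # (lower IQR), so max-IQR collapsing should recover the informative one
      features <- data.frame(probe_id = genes, gene_symbol = genes,
                             entrez_id = seq_len(cfg$n_genes),
                             stringsAsFactors = FALSE)
      if (cfg$multiprobe_fraction > 0) {
        n_mp <- round(cfg$multiprobe_fraction * cfg$n_genes)
        mp <- sample(cfg$n_genes, n_mp)
        extra_rows <- list(); extra_feat <- list()
        for (g in mp) {
          n_extra <- sample(1:2, 1)
          for (e in seq_len(n_extra)) {
            noisy <- loc[g] + scl[g] * (0.4 * z[g, ] + rnorm(n_s, 0, 0.4))
            pid <- sprintf("%s_p%d", genes[g], e + 1)
            extra_rows[[pid]] <- noisy
            extra_feat[[pid]] <- data.frame(probe_id = pid,
                                            gene_symbol = genes[g],
                                            entrez_id = g,
                                            stringsAsFactors = FALSE)
          }
        }
        rownames(x) <- sprintf("%s_p1", genes)
        features$probe_id <- rownames(x)
        x <- rbind(x, do.call(rbind, extra_rows))
        features <- rbind(features, do.call(rbind, extra_feat))
        rownames(features) <- NULL
      }

      clinical <- clinical_table(data.frame(
        sample_id = sample_ids, dataset_id = ds_id, sample_type = "tumor",
        age_at_diagnosis = round(rnorm(n_s, 63, 10), 1),
        grade = sample(1:4, n_s, replace = TRUE),
        stage = NA, er_status = NA, pgr_status = NA, her2_status = NA,
        subtype = paste0("subtype", subtype),
        days_to_death = round(time, 4),
        vital_status = ifelse(event == 1, "deceased", "living"),
        days_to_recurrence = NA, recurrence_status = NA, treatment = NA,
        stringsAsFactors = FALSE))
      expr <- expression_dataset(x, features, dataset_id = ds_id,
                                 cancer_type = types[t])
      cohorts[[ds_id]] <- list(expr = expr, clinical = clinical)
    }
  }
  out <- list(collection = cohort_collection(cohorts), truth = truth,
              achieved_censoring = achieved, config = cfg)
  if (cfg$duplicate_rate > 0) {
    dup <- inject_duplicates(out$collection, cfg$duplicate_rate,
                             seed = child_seed(cfg$seed, counter + 1L))
    out$collection <- dup$collection
    out$registry <- dup$registry
  }
  out
}

#' Inject near-duplicate samples across cohorts of a cancer type
#'
#' Clones samples from one cohort into another cohort of the same cancer
#' type, adding small Gaussian noise (Spearman rho of the pair stays above
#' 0.99 at genome scale), and returns the registry of injected pairs for
#' exact recall scoring of the duplicate filter.
#'
#' @param collection a `cohort_collection` with at least two cohorts per
#'   cancer type to inject into.
#' @param rate fraction of a cancer type's samples to clone, in \[0, 0.2\].
#' @param seed RNG seed.
#' @param noise_sd s.d. of the added noise (expression is on a scale with
#'   per-gene s.d. around 1).
#' @return list with `collection` (duplicates added) and `registry` (data
#'   frame `source_id`, `duplicate_id`, `source_dataset`, `target_dataset`,
#'   `cancer_type`).
#' @export
inject_duplicates <- function(collection, rate, seed = 1, noise_sd = 0.03) {
  stopifnot(rate >= 0, rate <= 0.2)
  registry <- data.frame(source_id = character(), duplicate_id = character(),
                         source_dataset = character(),
                         target_dataset = character(),
                         cancer_type = character(), stringsAsFactors = FALSE)
  if (rate == 0) return(list(collection = collection, registry = registry))
  set.seed(seed)
  cohorts <- unclass(collection)
  attr(cohorts, "grouping") <- NULL
  grouping <- attr(collection, "grouping")
  reg <- list()
  for (type in names(grouping)) {
    ids <- grouping[[type]]
    if (length(ids) < 2) next
    n_total <- sum(vapply(cohorts[ids], function(co) ncol(co$expr$exprs), 0))
    n_dup <- round(rate * n_total)
    for (d in seq_len(n_dup)) {
      src_ds <- sample(ids, 1)
      tgt_ds <- sample(setdiff(ids, src_ds), 1)
      src_co <- cohorts[[src_ds]]
      src_id <- sample(colnames(src_co$expr$exprs), 1)
      dup_id <- sprintf("%s_dup%03d", src_id, d)
      tgt_co <- cohorts[[tgt_ds]]
      tgt_probes <- rownames(tgt_co$expr$exprs)
      common <- intersect(rownames(src_co$expr$exprs), tgt_probes)
      newcol <- setNames(rep(NA_real_, length(tgt_probes)), tgt_probes)
      newcol[common] <- src_co$expr$exprs[common, src_id] +
        rnorm(length(common), 0, noise_sd)
      mat <- cbind(tgt_co$expr$exprs, newcol)
      colnames(mat)[ncol(mat)] <- dup_id
      cl_row <- src_co$clinical[src_co$clinical$sample_id == src_id, ]
      cl_row$sample_id <- dup_id
      cl_row$dataset_id <- tgt_ds
      clinical <- rbind(as.data.frame(tgt_co$clinical), cl_row)
      class(clinical) <- c("clinical_table", "data.frame")
      cohorts[[tgt_ds]] <- list(
        expr = expression_dataset(mat, tgt_co$expr$features,
                                  dataset_id = tgt_ds, cancer_type = type),
        clinical = clinical)
      reg[[length(reg) + 1L]] <- data.frame(
        source_id = src_id, duplicate_id = dup_id, source_dataset = src_ds,
        target_dataset = tgt_ds, cancer_type = type, stringsAsFactors = FALSE)
    }
  }
  if (length(reg)) registry <- do.call(rbind, c(reg, make.row.names = FALSE))
  list(collection = cohort_collection(cohorts), registry = registry)
}

#' Write the planted ground truth to TSV
#'
#' @param truth the `truth` component of [generate_collection()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
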