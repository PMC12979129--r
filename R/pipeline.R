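#' Assemble a pipeline run configuration
#'
#' Merges a YAML configuration file (optional) and override values over the
#' package defaults.  Defaults encode the derivation thresholds of the
#' consensus method: fold change 1.5, raw p < 0.05, votes >= 5.
#'
#' @param path optional YAML file.
#' @param overrides named list taking precedence over the file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    fold_threshold = 1.5, alpha = 0.05, use_fdr = FALSE, min_votes = 5,
    relative_votes = FALSE, drop_discordant = FALSE,
    quantile = TRUE, min_cpm = 1, min_samples = NULL,
    seed = 1, top_k = 50,
    gsea = list(weight = 1, n_perm = 1000, min_size = 5, max_size = NULL),
    simulate = list(n_datasets = 11, n_intensity = 6, n_counts = 5,
                    n_genes = 2000, n_per_group = 4, zinc_effect_log2 = 1.5,
                    n_zinc = 9, n_stress = 6, high_dose_datasets = 3,
                    measured_fraction = 0.85),
    treatment_datasets = NULL, depletion_datasets = NULL,
    cohorts = NULL, stress_gmt = NULL, pathway_gmt = NULL,
    signature = NULL, signature_file = NULL,
    merge_cohorts = FALSE, control = NULL)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  if (cfg$fold_threshold <= 0 || cfg$alpha <= 0 || cfg$min_votes < 1)
    stop("thresholds must be positive and min_votes >= 1")
  class(cfg) <- "run_config"
  cfg
}

.load_dataset_entry <- function(entry) {
  for (f in c("matrix", "metadata")) {
    if (is.null(entry[[f]])) stop("dataset entry lacks '", f, "'")
    if (!file.exists(entry[[f]])) stop("input path not found: ", entry[[f]])
  }
  read_expression_matrix(entry$matrix, platform = entry$platform %||% "intensity",
                         metadata_path = entry$metadata,
                         dataset_id = entry$id %||% NULL)
}

# TSV writer with fixed formatting so identical runs are byte-identical
.write_tsv <- function(df, path, digits = 10) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.run_summary <- function(config, stage, counts, seed) {
  list(stage = stage,
       package = "zincsig",
       version = as.character(utils::packageVersion("zincsig")),
       seed = seed,
       config = unclass(config),
       counts = counts)
}

#' Write synthetic fixtures for a full pipeline run
#'
#' Simulates the treatment panel, one depletion dataset, and two disease
#' cohorts, and writes them as matrix/metadata TSVs plus stress-response and
#' pathway GMT files under `outdir`.  Returns a configuration pointing at
#' the written files, ready for [run_derive()]/[run_all()].
#'
#' @param config a `run_config` (simulation sizes under `$simulate`).
#' @param outdir output directory (created if needed).
#' @param seed RNG seed (defaults to `config$seed`).
#' @return The updated `run_config`, invisibly; side effect: files under
#'   `outdir`.
#' @export
run_simulate <- function(config = read_run_config(), outdir, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- seed %||% config$seed
  sp <- config$simulate
  sim <- simulate_treatment_datasets(
    n_datasets = sp$n_datasets, n_intensity = sp$n_intensity,
    n_counts = sp$n_counts, n_genes = sp$n_genes,
    n_per_group = sp$n_per_group, zinc_effect_log2 = sp$zinc_effect_log2,
    n_zinc = sp$n_zinc, n_stress = sp$n_stress,
    high_dose_datasets = sp$high_dose_datasets,
    measured_fraction = sp$measured_fraction, seed = seed)
  treatment <- list()
  for (d in sim$datasets) {
    mfile <- file.path(outdir, paste0(d$dataset_id, "_matrix.tsv"))
    mdfile <- file.path(outdir, paste0(d$dataset_id, "_meta.tsv"))
    write_expression_matrix(d, mfile, mdfile)
    treatment[[length(treatment) + 1L]] <-
      list(id = d$dataset_id, platform = d$platform, matrix = mfile,
           metadata = mdfile)
  }
  dep <- simulate_depletion_dataset(n_genes = sp$n_genes,
                                    n_zinc = sp$n_zinc, seed = seed + 1L)
  dep_m <- file.path(outdir, "DEP1_matrix.tsv")
  dep_md <- file.path(outdir, "DEP1_meta.tsv")
  write_expression_matrix(dep$dataset, dep_m, dep_md)
  cohorts <- list()
  module_sets <- list()
  for (i in 1:2) {
    co <- simulate_disease_cohort(n_genes = sp$n_genes,
                                  signature = .zinc_pool[seq_len(sp$n_zinc)],
                                  dataset_id = sprintf("COHORT%d", i),
                                  seed = seed + 10L + i)
    cm <- file.path(outdir, sprintf("COHORT%d_matrix.tsv", i))
    cmd <- file.path(outdir, sprintf("COHORT%d_meta.tsv", i))
    write_expression_matrix(co$dataset, cm, cmd)
    cohorts[[i]] <- list(id = co$dataset$dataset_id, platform = "intensity",
                         matrix = cm, metadata = cmd)
    module_sets$ACUTE_PHASE_MODULE <- co$truth$module_genes
  }
  stress_gmt <- file.path(outdir, "stress_response.gmt")
  write_gmt(default_stress_sets(), stress_gmt)
  pathway_gmt <- file.path(outdir, "pathways.gmt")
  write_gmt(gene_sets(module_sets), pathway_gmt)
  .write_json(list(truth = list(zinc_genes = sim$truth$zinc_genes,
                                stress_genes = sim$truth$stress_genes,
                                high_dose_datasets = sim$truth$high_dose_datasets,
                                depletion = dep$truth["depletion_effect_log2"]),
                   seed = seed),
              file.path(outdir, "simulation_truth.json"))
  config$treatment_datasets <- treatment
  config$depletion_datasets <- list(list(id = "DEP1", platform = "intensity",
                                         matrix = dep_m, metadata = dep_md))
  config$cohorts <- cohorts
  config$stress_gmt <- stress_gmt
  config$pathway_gmt <- pathway_gmt
  invisible(config)
}

#' Derive the signature from configured datasets
#'
#' Loads the configured treatment (and optional depletion) datasets, runs
#' [derive_signature()] with the configured thresholds, and writes the
#' signature table, the consensus vote table, and a JSON run summary.
#'
#' @param config a `run_config` listing `treatment_datasets` (and optional
#'   `depletion_datasets`, `stress_gmt`).
#' @param outdir output directory.
#' @return The `zinc_signature`, invisibly; side effect: `signature.tsv`,
#'   `consensus.tsv`, `derive_summary.json` under `outdir`.
#' @export
run_derive <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (length(config$treatment_datasets %||% list()) < 2L)
    stop("derive requires at least 2 configured treatment datasets")
  message("derive: loading ", length(config$treatment_datasets), " treatment dataset(s)")
  datasets <- lapply(config$treatment_datasets, .load_dataset_entry)
  depletion <- lapply(config$depletion_datasets %||% list(), .load_dataset_entry)
  stress_sets <- if (!is.null(config$stress_gmt)) read_gmt(config$stress_gmt) else NULL
  sig <- derive_signature(datasets, depletion = depletion,
                          stress_sets = stress_sets,
                          fold_threshold = config$fold_threshold,
                          alpha = config$alpha, use_fdr = config$use_fdr,
                          min_votes = config$min_votes,
                          relative_votes = config$relative_votes,
                          drop_discordant = config$drop_discordant,
                          control = config$control,
                          quantile = config$quantile,
                          min_cpm = config$min_cpm,
                          min_samples = config$min_samples)
  tab <- sig$table
  if (nrow(tab)) {
    tab$datasets_up <- vapply(tab$gene, function(g)
      paste(sig$consensus$datasets[sig$consensus$up[g, ]], collapse = ","),
      character(1))
  } else {
    tab$datasets_up <- character(0)
  }
  .write_tsv(tab[, c("gene", "votes_up", "n_measured", "mean_log2fc",
                     "datasets_up", "stress_flagged", "depletion_status")],
             file.path(outdir, "signature.tsv"))
  .write_tsv(sig$consensus$table, file.path(outdir, "consensus.tsv"))
  counts <- list(datasets = length(datasets),
                 depletion_datasets = length(depletion),
                 genes_union = nrow(sig$consensus$table),
                 preliminary = length(sig$preliminary),
                 stress_flagged = length(sig$stress$flagged),
                 signature = length(sig$genes))
  .write_json(.run_summary(config, "derive", counts, config$seed),
              file.path(outdir, "derive_summary.json"))
  message("derive: ", length(sig$genes), " signature gene(s)")
  invisible(sig)
}

.resolve_signature <- function(config, outdir = NULL) {
  if (!is.null(config$signature)) return(unique(toupper(config$signature)))
  file <- config$signature_file
  if (is.null(file) && !is.null(outdir) &&
      file.exists(file.path(outdir, "signature.tsv")))
    file <- file.path(outdir, "signature.tsv")
  if (is.null(file)) stop("no signature configured (set `signature` or `signature_file`)")
  if (!file.exists(file)) stop("signature file not found: ", file)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  sf <- as.logical(tab$stress_flagged %||% rep(FALSE, nrow(tab)))
  sf[is.na(sf)] <- FALSE
  unique(toupper(tab$gene[!sf]))
}

#' Score configured cohorts with the signature
#'
#' @param config a `run_config` with `cohorts` plus a signature (inline
#'   `signature`, `signature_file`, or a previous [run_derive()] output in
#'   `outdir`).
#' @param outdir output directory.
#' @return Named list of `scored_cohort` objects, invisibly; side effect:
#'   per-cohort `scores_<id>.tsv` and a combined `score_summary.json`.
#' @export
run_score <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!length(config$cohorts %||% list())) stop("no cohorts configured")
  genes <- .resolve_signature(config, outdir)
  out <- list()
  summaries <- list()
  for (entry in config$cohorts) {
    ds <- .load_dataset_entry(entry)
    missing <- setdiff(genes, rownames(ds$values))
    if (length(missing) > ceiling(0.5 * length(genes)))
      stop("signature genes absent from cohort ", ds$dataset_id, ": ",
           paste(missing, collapse = ", "))
    sc <- score_cohort(ds, genes, control = config$control)
    out[[ds$dataset_id]] <- sc
    .write_tsv(data.frame(sample = sc$sample, score = unname(sc$score),
                          quartile = unname(sc$quartile),
                          group = unname(sc$group)),
               file.path(outdir, sprintf("scores_%s.tsv", ds$dataset_id)))
    summaries[[ds$dataset_id]] <- list(
      n = length(sc$score),
      score_log2fc = if (!is.null(sc$log2fc)) sc$log2fc$score_log2fc else NULL,
      per_gene_log2fc = if (!is.null(sc$log2fc))
        stats::setNames(as.list(sc$log2fc$per_gene$log2fc),
                        sc$log2fc$per_gene$gene) else NULL,
      quartile_test_p = if (!is.null(sc$quartile_test)) sc$quartile_test$p else NULL,
      correlations = if (!is.null(sc$correlations))
        lapply(seq_len(nrow(sc$correlations)), function(i)
          as.list(sc$correlations[i, ])) else NULL)
  }
  .write_json(.run_summary(config, "score",
                           list(cohorts = length(out), signature = length(genes),
                                results = summaries), config$seed),
              file.path(outdir, "score_summary.json"))
  message("score: ", length(out), " cohort(s) scored")
  invisible(out)
}

#' Genome-wide association of the score with expression
#'
#' Scores every configured cohort (optionally also the batch-merged union),
#' correlates the score against all genes, writes per-cohort rankings, the
#' cross-dataset top-gene consensus, and pre-ranked GSEA results for the
#' configured pathway sets.
#'
#' @param config a `run_config` with `cohorts`, a signature, and optionally
#'   `pathway_gmt`, `merge_cohorts`, `top_k`, `gsea`.
#' @param outdir output directory.
#' @return List with `rankings`, `consensus`, `enrichment`, invisibly; side
#'   effect: `ranking_<id>.tsv`, `consensus_top.tsv`, `enrichment_<id>.tsv`,
#'   `associate_summary.json`.
#' @export
run_associate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!length(config$cohorts %||% list())) stop("no cohorts configured")
  genes <- .resolve_signature(config, outdir)
  cohorts <- lapply(config$cohorts, .load_dataset_entry)
  if (isTRUE(config$merge_cohorts) && length(cohorts) > 1L)
    cohorts <- c(cohorts, list(merge_batches(cohorts)))
  sets <- if (!is.null(config$pathway_gmt)) read_gmt(config$pathway_gmt) else NULL
  rankings <- list()
  enrichment <- list()
  for (ds in cohorts) {
    sc <- compute_score(ds, genes)
    rk <- correlate_score_genomewide(ds, sc)
    rankings[[ds$dataset_id]] <- rk
    .write_tsv(as.data.frame(rk),
               file.path(outdir, sprintf("ranking_%s.tsv", ds$dataset_id)))
    if (!is.null(sets) && length(sets)) {
      en <- preranked_gsea(rk, sets, weight_p = config$gsea$weight,
                           n_perm = config$gsea$n_perm, seed = config$seed,
                           min_size = config$gsea$min_size,
                           max_size = config$gsea$max_size)
      enrichment[[ds$dataset_id]] <- en
      .write_tsv(en, file.path(outdir, sprintf("enrichment_%s.tsv", ds$dataset_id)))
    }
  }
  consensus <- NULL
  if (length(rankings) >= 2L) {
    consensus <- cross_dataset_top(rankings, k = config$top_k)
    .write_tsv(consensus, file.path(outdir, "consensus_top.tsv"))
  }
  counts <- list(cohorts = length(cohorts),
                 genes_ranked = vapply(rankings, nrow, integer(1)),
                 sets_tested = if (length(enrichment))
                   vapply(enrichment, nrow, integer(1)) else NULL,
                 top_k = config$top_k)
  .write_json(.run_summary(config, "associate", counts, config$seed),
              file.path(outdir, "associate_summary.json"))
  message("associate: ", length(rankings), " ranking(s) written")
  invisible(list(rankings = rankings, consensus = consensus,
                 enrichment = enrichment))
}

#' Run the full pipeline (simulate, derive, score, associate)
#'
#' Deterministic end-to-end run: with `simulate = TRUE` the synthetic
#' fixtures are generated first, then the signature is derived, cohorts are
#' scored, and the association stage runs, all seeded from `config$seed`.
#' Two runs with identical configuration and seed produce byte-identical
#' outputs.
#'
#' @param config a `run_config`.
#' @param outdir output directory.
#' @param simulate generate synthetic inputs first (default `TRUE` when no
#'   treatment datasets are configured).
#' @return List with `signature`, `scores`, `association`, invisibly.
#' @export
run_all <- function(config = read_run_config(), outdir,
                    simulate = is.null(config$treatment_datasets)) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) config <- run_simulate(config, file.path(outdir, "inputs"))
  sig <- run_derive(config, outdir)
  if (is.null(config$signature) && is.null(config$signature_file))
    config$signature <- if (length(sig$genes)) sig$genes else core_signature_genes()
  scores <- run_score(config, outdir)
  assoc <- run_associate(config, outdir)
  .write_json(.run_summary(config, "all",
                           list(signature = length(sig$genes),
                                cohorts = length(scores)), config$seed),
              file.path(outdir, "run_summary.json"))
  invisible(list(signature = sig, scores = scores, association = assoc))
}
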