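#' Tally up-regulation votes across datasets
#'
#' Combines per-dataset differential-expression calls into a gene-by-dataset
#' membership table: for every gene, the number of datasets voting it
#' up-regulated, the datasets in which it was measured at all, and the
#' per-dataset effect sizes.  Unmeasured genes contribute neither votes nor
#' any denominator under the default absolute-threshold convention.
#'
#' @param de_results named list of per-dataset DE data.frames
#'   (see [run_de()]); names are dataset ids.
#' @return A `consensus_table`: list with `table` (data.frame `gene`,
#'   `votes_up`, `n_measured`, `mean_log2fc`), logical matrices `up` and
#'   `measured` (genes x datasets), numeric matrices `log2fc` and `p`, and
#'   `datasets` (ids).
#' @export
vote_count <- function(de_results) {
  stopifnot(length(de_results) >= 2L)
  ids <- names(de_results)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(de_results, function(d) attr(d, "dataset_id") %||% "", character(1))
  if (any(!nzchar(ids))) stop("de_results must be a named list of DE tables")
  names(de_results) <- ids
  genes <- sort(unique(unlist(lapply(de_results, `[[`, "gene"))))
  k <- length(genes); n <- length(ids)
  up <- measured <- matrix(FALSE, k, n, dimnames = list(genes, ids))
  lfc <- pmat <- matrix(NA_real_, k, n, dimnames = list(genes, ids))
  for (j in seq_len(n)) {
    d <- de_results[[j]]
    i <- match(d$gene, genes)
    measured[i, j] <- d$measured
    up[i, j] <- d$up
    lfc[i, j] <- ifelse(d$measured, d$log2fc, NA_real_)
    pmat[i, j] <- ifelse(d$measured, d$p, NA_real_)
  }
  mean_lfc <- rowMeans(lfc, na.rm = TRUE)
  mean_lfc[is.nan(mean_lfc)] <- NA_real_
  tab <- data.frame(gene = genes,
                    votes_up = rowSums(up),
                    n_measured = rowSums(measured),
                    mean_log2fc = mean_lfc,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, up = up, measured = measured,
                 log2fc = lfc, p = pmat, datasets = ids),
            class = "consensus_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("<consensus_table> %d genes x %d datasets\n",
              nrow(x$table), length(x$datasets)))
  top <- x$table[order(-x$table$votes_up, -x$table$mean_log2fc, x$table$gene), ]
  print(utils::head(top, 10), row.names = FALSE)
  invisible(x)
}

#' Assemble the preliminary signature by vote threshold
#'
#' Genes voted up-regulated in at least `min_votes` datasets (absolute
#' threshold over all datasets, not just those measuring the gene), ordered
#' by votes descending, then mean log2 fold change descending, then symbol.
#' A relative mode gates on the fraction of *measured* datasets instead.
#'
#' @param consensus a `consensus_table` from [vote_count()].
#' @param min_votes vote threshold (default 5).
#' @param relative if `TRUE`, include genes up in at least
#'   `min_votes / n_datasets` of the datasets in which they are measured.
#' @return Character vector of gene symbols (possibly empty, with warning).
#' @export
assemble_preliminary <- function(consensus, min_votes = 5, relative = FALSE) {
  stopifnot(inherits(consensus, "consensus_table"))
  tab <- consensus$table
  if (relative) {
    frac <- min_votes / length(consensus$datasets)
    sel <- tab$n_measured > 0 & tab$votes_up / pmax(tab$n_measured, 1L) >= frac
  } else {
    sel <- tab$votes_up >= min_votes
  }
  tab <- tab[sel, , drop = FALSE]
  if (!nrow(tab)) {
    warning("empty preliminary signature at min_votes = ", min_votes)
    return(character(0))
  }
  tab <- tab[order(-tab$votes_up, -tab$mean_log2fc, tab$gene), ]
  tab$gene
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= k)` of drawing at least the observed
#' overlap `k` between `query` and `reference` in `|query|` draws without
#' replacement from a universe containing `|reference|` successes.
#'
#' @param query character vector of genes (must lie within `universe`).
#' @param reference character vector of genes defining the tested set;
#'   silently restricted to the universe.
#' @param universe character vector of all testable genes.
#' @return List with `overlap` (k) and `p`.
#' @export
ora_hypergeom <- function(query, reference, universe) {
  if (!length(universe)) stop("empty universe")
  query <- unique(toupper(query))
  reference <- unique(toupper(reference))
  universe <- unique(toupper(universe))
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query genes not in universe: ", paste(bad, collapse = ", "))
  reference <- intersect(reference, universe)
  k <- length(intersect(query, reference))
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(query), lower.tail = FALSE)
  list(overlap = k, p = min(p, 1))
}

#' Remove stress-response transcripts from a preliminary signature
#'
#' Two actions: (a) any preliminary gene that is a member of any configured
#' stress set is flagged and removed; (b) when per-dataset up-regulated gene
#' lists are supplied, each dataset's full up list is tested for stress-set
#' over-representation ([ora_hypergeom()], BH-adjusted across sets within
#' each dataset) and datasets reaching q < `alpha` are reported as
#' stress-confounded.  Reporting does not retract their votes.
#'
#' @param preliminary character vector from [assemble_preliminary()].
#' @param stress_sets a `gene_set_collection` of stress-response sets, or
#'   `NULL` (identity, with warning).
#' @param per_dataset_up optional named list: dataset id -> up-regulated
#'   gene symbols.
#' @param per_dataset_universe optional named list: dataset id -> measured
#'   gene symbols (the ORA universe).
#' @param alpha BH-adjusted significance threshold for the dataset report.
#' @return List: `genes` (kept), `flagged` (removed), `report` (data.frame
#'   `dataset`, `set`, `overlap`, `p`, `q`), `confounded` (dataset ids).
#' @export
filter_stress <- function(preliminary, stress_sets = NULL,
                          per_dataset_up = NULL, per_dataset_universe = NULL,
                          alpha = 0.05) {
  stopifnot(length(preliminary) >= 1L)
  if (is.null(stress_sets) || length(stress_sets) == 0L) {
    warning("no stress sets configured; signature passed through unfiltered")
    return(list(genes = preliminary, flagged = character(0),
                report = NULL, confounded = character(0)))
  }
  stress_union <- unique(toupper(unlist(stress_sets)))
  flagged <- preliminary[preliminary %in% stress_union]
  kept <- preliminary[!preliminary %in% stress_union]
  report <- NULL; confounded <- character(0)
  if (!is.null(per_dataset_up)) {
    rows <- list()
    for (id in names(per_dataset_up)) {
      uni <- if (!is.null(per_dataset_universe)) per_dataset_universe[[id]]
             else unique(c(per_dataset_up[[id]], stress_union))
      for (nm in names(stress_sets)) {
        o <- ora_hypergeom(per_dataset_up[[id]], stress_sets[[nm]], uni)
        rows[[length(rows) + 1L]] <-
          data.frame(dataset = id, set = nm, overlap = o$overlap, p = o$p,
                     stringsAsFactors = FALSE)
      }
    }
    report <- do.call(rbind, rows)
    report$q <- NA_real_
    for (id in unique(report$dataset)) {
      sel <- report$dataset == id
      report$q[sel] <- bh_adjust(report$p[sel])
    }
    confounded <- unique(report$dataset[report$q < alpha])
  }
  list(genes = kept, flagged = flagged, report = report,
       confounded = confounded)
}

#' Validate signature genes against zinc-depletion datasets
#'
#' A signature gene is `validated` when it is called down-regulated in at
#' least one depletion dataset and up-regulated in none, `discordant` when
#' any depletion dataset calls it up-regulated, and `unmeasured` otherwise.
#' Discordant genes are reported, not removed (removal is the caller's
#' choice).
#'
#' @param genes character vector of signature genes.
#' @param depletion_results named list of DE data.frames from depletion
#'   contrasts (depleted minus control).
#' @return data.frame `gene`, `depletion_status`
#'   (factor: validated/discordant/unmeasured).
#' @export
validate_with_depletion <- function(genes, depletion_results) {
  stopifnot(length(depletion_results) >= 1L)
  status <- vapply(genes, function(g) {
    up_any <- FALSE; down_any <- FALSE
    for (d in depletion_results) {
      i <- match(g, d$gene)
      if (is.na(i) || !d$measured[i]) next
      if (d$up[i]) up_any <- TRUE
      if (d$down[i]) down_any <- TRUE
    }
    if (up_any) "discordant"
    else if (down_any) "validated"
    else "unmeasured"
  }, character(1))
  data.frame(gene = genes,
             depletion_status = factor(status, levels = c("validated", "discordant", "unmeasured")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive a consensus zinc signature from treatment datasets
#'
#' The central fitting function of the package.  Runs per-dataset moderated-t
#' differential expression ([run_de()]) on every zinc-treatment dataset,
#' tallies up-regulation votes ([vote_count()]), assembles the preliminary
#' signature at the vote threshold ([assemble_preliminary()]), removes
#' stress-response transcripts ([filter_stress()]), and, when depletion
#' datasets are supplied, annotates each remaining gene with its
#' reciprocal-regulation status ([validate_with_depletion()]).
#'
#' @param datasets list of treatment `zinc_dataset` objects (two groups:
#'   treated vs control).
#' @param depletion optional list of depletion `zinc_dataset` objects
#'   (depleted vs control).
#' @param stress_sets a `gene_set_collection` of stress-response gene sets;
#'   `NULL` disables stress filtering (see [default_stress_sets()]).
#' @param fold_threshold,alpha,use_fdr regulation-call settings
#'   (defaults 1.5, 0.05, raw p).
#' @param min_votes vote threshold for the preliminary signature (default 5).
#' @param relative_votes use the relative vote denominator
#'   (see [assemble_preliminary()]).
#' @param drop_discordant remove genes the depletion data contradicts
#'   (default `FALSE`: discordant genes are retained and flagged).
#' @param control control group level, shared across datasets (inferred
#'   when `NULL`).
#' @param quantile quantile-normalize intensity data (default `TRUE`).
#' @param min_cpm,min_samples count-filter settings.
#' @return An object of class `zinc_signature`: list with `genes` (the final
#'   signature), `table` (per-gene provenance: votes, datasets measured,
#'   mean log2fc, stress/depletion status), `preliminary`, `consensus`
#'   (the full `consensus_table`), `de`, `depletion_de`, `stress` (filter
#'   report) and `params`.
#' @examples
#' sim <- simulate_treatment_datasets(n_datasets = 4, n_intensity = 2,
#'                                    n_counts = 2, n_genes = 300, seed = 1)
#' sig <- derive_signature(sim$datasets, min_votes = 3,
#'                         stress_sets = default_stress_sets())
#' print(sig)
#' @export
derive_signature <- function(datasets, depletion = list(), stress_sets = NULL,
                             fold_threshold = 1.5, alpha = 0.05,
                             use_fdr = FALSE, min_votes = 5,
                             relative_votes = FALSE, drop_discordant = FALSE,
                             control = NULL, quantile = TRUE,
                             min_cpm = 1, min_samples = NULL) {
  stopifnot(length(datasets) >= 2L)
  de <- lapply(datasets, run_de, fold_threshold = fold_threshold,
               alpha = alpha, use_fdr = use_fdr, quantile = quantile,
               control = control, min_cpm = min_cpm, min_samples = min_samples)
  names(de) <- vapply(datasets, function(d) d$dataset_id, character(1))
  consensus <- vote_count(de)
  preliminary <- assemble_preliminary(consensus, min_votes = min_votes,
                                      relative = relative_votes)
  if (!length(preliminary)) {
    genes <- character(0)
    stress <- list(genes = character(0), flagged = character(0),
                   report = NULL, confounded = character(0))
  } else {
    per_up <- lapply(de, function(d) d$gene[d$up])
    per_uni <- lapply(de, function(d) d$gene[d$measured])
    stress <- if (is.null(stress_sets) || length(stress_sets) == 0L)
      list(genes = preliminary, flagged = character(0), report = NULL,
           confounded = character(0))
    else filter_stress(preliminary, stress_sets, per_dataset_up = per_up,
                       per_dataset_universe = per_uni, alpha = alpha)
    genes <- stress$genes
  }
  depletion_de <- NULL
  depl_status <- NULL
  if (length(depletion)) {
    depletion_de <- lapply(depletion, run_de, fold_threshold = fold_threshold,
                           alpha = alpha, use_fdr = use_fdr,
                           quantile = quantile, control = control,
                           min_cpm = min_cpm, min_samples = min_samples)
    names(depletion_de) <- vapply(depletion, function(d) d$dataset_id, character(1))
    if (length(genes)) {
      depl_status <- validate_with_depletion(genes, depletion_de)
      if (drop_discordant)
        genes <- depl_status$gene[depl_status$depletion_status != "discordant"]
    }
  }
  tab <- consensus$table[match(genes, consensus$table$gene), , drop = FALSE]
  tab[["stress_flagged"]] <- rep(FALSE, nrow(tab))
  tab[["depletion_status"]] <- if (is.null(depl_status)) rep(NA_character_, nrow(tab))
                               else as.character(depl_status$depletion_status[match(genes, depl_status$gene)])
  flagged_tab <- consensus$table[match(stress$flagged, consensus$table$gene), , drop = FALSE]
  flagged_tab[["stress_flagged"]] <- rep(TRUE, nrow(flagged_tab))
  flagged_tab[["depletion_status"]] <- rep(NA_character_, nrow(flagged_tab))
  structure(list(genes = genes,
                 table = rbind(tab, flagged_tab),
                 preliminary = preliminary,
                 consensus = consensus,
                 de = de,
                 depletion_de = depletion_de,
                 stress = stress,
                 params = list(fold_threshold = fold_threshold, alpha = alpha,
                               use_fdr = use_fdr, min_votes = min_votes,
                               relative_votes = relative_votes,
                               drop_discordant = drop_discordant,
                               n_datasets = length(datasets),
                               n_depletion = length(depletion))),
            class = "zinc_signature")
}

#' @export
print.zinc_signature <- function(x, ...) {
  cat(sprintf("Zinc signature: %d gene(s) (from %d preliminary, %d dataset%s, vote threshold %d)\n",
              length(x$genes), length(x$preliminary), x$params$n_datasets,
              if (x$params$n_datasets == 1) "" else "s", x$params$min_votes))
  if (length(x$genes)) {
    tab <- x$table[match(x$genes, x$table$gene),
                   c("gene", "votes_up", "n_measured", "mean_log2fc", "depletion_status")]
    print(tab, row.names = FALSE, digits = 3)
  }
  if (length(x$stress$flagged))
    cat("Stress-filtered: ", paste(x$stress$flagged, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.zinc_signature <- function(object, ...) {
  print(object)
  p <- object$params
  cat(sprintf("Calls: fold >= %.2g, %s < %.2g\n", p$fold_threshold,
              if (p$use_fdr) "FDR" else "p", p$alpha))
  if (length(object$stress$confounded))
    cat("Stress-confounded datasets: ",
        paste(object$stress$confounded, collapse = ", "), "\n", sep = "")
  if (!is.null(object$stress$report)) {
    cat("Per-dataset stress enrichment (q < 0.05 flagged):\n")
    print(object$stress$report, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Stress-response gene sets shipped with the package
#'
#' A small heat-shock / DNA-damage-response collection (HSPA6, DDIT3,
#' DNAJB1, ...) used to purge stress transcripts induced only by
#' supraphysiological zinc doses or ionophores from preliminary signatures.
#'
#' @return A `gene_set_collection`.
#' @export
default_stress_sets <- function() {
  read_gmt(system.file("extdata", "stress_response.gmt", package = "zincsig"))
}

#' Core zinc signature genes shipped with the package
#'
#' The six metallothionein/transporter members documented as the floor of
#' the validated signature (MT1A, MT1E, MT1F, MT1G, MT1M, SLC30A1); the full
#' signature is a configuration input and is normally derived from data with
#' [derive_signature()].
#'
#' @return Character vector of gene symbols.
#' @export
core_signature_genes <- function() {
  readLines(system.file("extdata", "zinc_signature_core.txt", package = "zincsig"),
            warn = FALSE)
}
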