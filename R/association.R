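#' Merge expression datasets with a location-scale batch adjustment
#'
#' Restricts the input datasets to their common genes, quantile-normalizes
#' each dataset, then removes batch effects with a per-gene location-scale
#' adjustment: within every batch each gene is standardized to the pooled
#' per-gene mean and standard deviation.  A gene with zero within-batch
#' variance gets a location-only adjustment for that batch.  This is a
#' deliberate simplification of full empirical-Bayes batch correction; the
#' downstream association analyses consume ranks and correlations, which are
#' robust to the difference.
#'
#' @param datasets list of normalized (log2-scale) `zinc_dataset` objects.
#' @param min_common minimum number of shared genes required (default 100).
#' @param quantile quantile-normalize each dataset before merging.
#' @return A merged `zinc_dataset` whose batch labels are the source
#'   dataset ids.
#' @export
merge_batches <- function(datasets, min_common = 100, quantile = TRUE) {
  stopifnot(length(datasets) >= 1L)
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (length(common) < min_common)
    stop("datasets share only ", length(common), " genes (< ", min_common, ")")
  common <- sort(common)
  mats <- lapply(datasets, function(d) {
    m <- d$values[common, , drop = FALSE]
    if (quantile) m <- quantile_normalize(m)
    m
  })
  X <- do.call(cbind, mats)
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  batch <- rep(ids, vapply(mats, ncol, integer(1)))
  names(batch) <- colnames(X)
  if (length(datasets) > 1L) {
    mu <- rowMeans(X, na.rm = TRUE)
    sg <- sqrt(.row_vars(X))
    for (b in unique(batch)) {
      cols <- which(batch == b)
      Xb <- X[, cols, drop = FALSE]
      mb <- rowMeans(Xb, na.rm = TRUE)
      sb <- sqrt(.row_vars(Xb))
      scale_ok <- is.finite(sb) & sb > 1e-12 & is.finite(sg) & sg > 1e-12
      adj <- Xb - mb + mu
      adj[scale_ok, ] <- (Xb[scale_ok, , drop = FALSE] - mb[scale_ok]) /
        sb[scale_ok] * sg[scale_ok] + mu[scale_ok]
      X[, cols] <- adj
    }
  }
  groups <- do.call(c, lapply(datasets, function(d) d$groups))
  covs <- lapply(datasets, function(d) d$covariates)
  covariates <- NULL
  if (any(!vapply(covs, is.null, logical(1)))) {
    allcols <- unique(unlist(lapply(covs, colnames)))
    covariates <- do.call(rbind, lapply(seq_along(datasets), function(i) {
      cv <- covs[[i]]
      out <- as.data.frame(matrix(NA_real_, ncol(datasets[[i]]$values),
                                  length(allcols),
                                  dimnames = list(colnames(datasets[[i]]$values), allcols)))
      if (!is.null(cv)) out[rownames(cv), colnames(cv)] <- cv
      out
    }))
  }
  expression_dataset(X, "intensity", groups, dataset_id = "merged",
                     batch = batch, covariates = covariates, log_scale = TRUE)
}

.row_vars <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ifelse(n > 1, rowSums((m - mu)^2, na.rm = TRUE) / (n - 1), NA_real_)
}

#' Genome-wide correlation of signature score with expression
#'
#' Pearson correlation of the per-sample score vector against every gene in
#' the dataset (pairwise-complete), with two-sided p-values from the t
#' transform.  Genes with zero variance are reported with missing r and no
#' rank; ranking is by r descending, ties broken by symbol.
#'
#' @param dataset normalized `zinc_dataset`.
#' @param scores named per-sample score vector (see [compute_score()]).
#' @return A `correlation_ranking` data.frame: `gene`, `r`, `p`, `n`,
#'   `rank`, ordered by rank; attribute `dataset_id`.
#' @export
correlate_score_genomewide <- function(dataset, scores) {
  stopifnot(inherits(dataset, "zinc_dataset"))
  X <- dataset$values[, names(scores), drop = FALSE]
  if (ncol(X) < 3L) stop("genome-wide correlation requires at least 3 samples")
  r <- suppressWarnings(as.vector(stats::cor(t(X), scores,
                                             use = "pairwise.complete.obs")))
  nv <- rowSums(!is.na(X) & rep(!is.na(scores), each = nrow(X)))
  tstat <- r * sqrt(pmax(nv - 2, 0) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = pmax(nv - 2, 1), lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  genes <- rownames(X)
  out <- data.frame(gene = genes, r = r, p = p, n = nv,
                    stringsAsFactors = FALSE, row.names = NULL)
  ok <- !is.na(out$r)
  ord <- order(-out$r[ok], out$gene[ok])
  out$rank <- NA_integer_
  out$rank[which(ok)[ord]] <- seq_len(sum(ok))
  out <- out[order(out$rank, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dataset_id") <- dataset$dataset_id
  class(out) <- c("correlation_ranking", "data.frame")
  out
}

#' Cross-dataset consensus of top score-correlated genes
#'
#' Genes ranked in every input correlation ranking are ordered by their mean
#' rank across rankings; the top `k` are reported with per-dataset r values.
#'
#' @param rankings list of `correlation_ranking` objects.
#' @param k number of consensus genes to report (default 50; truncated with
#'   a warning when fewer genes are common to all rankings).
#' @param exclude optional genes to drop (e.g. the signature genes
#'   themselves).
#' @return data.frame `gene`, `mean_rank`, one `r.<dataset>` column per
#'   ranking.
#' @export
cross_dataset_top <- function(rankings, k = 50, exclude = NULL) {
  stopifnot(length(rankings) >= 2L)
  ids <- vapply(seq_along(rankings), function(i)
    attr(rankings[[i]], "dataset_id") %||% paste0("dataset", i), character(1))
  common <- Reduce(intersect, lapply(rankings, function(r) r$gene[!is.na(r$rank)]))
  if (!is.null(exclude)) common <- setdiff(common, toupper(exclude))
  if (k > length(common)) {
    warning("k = ", k, " exceeds the ", length(common),
            " genes common to all rankings; truncating")
    k <- length(common)
  }
  rank_mat <- vapply(rankings, function(r) r$rank[match(common, r$gene)],
                     numeric(length(common)))
  r_mat <- vapply(rankings, function(r) r$r[match(common, r$gene)],
                  numeric(length(common)))
  mean_rank <- rowMeans(rank_mat)
  o <- order(mean_rank, common)
  out <- data.frame(gene = common[o], mean_rank = mean_rank[o],
                    stringsAsFactors = FALSE, row.names = NULL)
  r_cols <- as.data.frame(r_mat[o, , drop = FALSE])
  colnames(r_cols) <- paste0("r.", ids)
  out <- cbind(out, r_cols)
  utils::head(out, k)
}

# walking-sum enrichment score for hit positions `pos` (sorted) in a ranked
# list of length N; hit increments |r|^p normalized by total hit weight,
# miss decrement 1/(N - m); ES = signed extremum of the walk
.gsea_es <- function(pos, absr, weight_p, N) {
  m <- length(pos)
  w <- if (weight_p == 0) rep(1, m) else absr[pos]^weight_p
  W <- sum(w)
  if (W <= 0) { w <- rep(1, m); W <- m }
  cw <- cumsum(w) / W
  miss <- 1 / (N - m)
  deficit <- (pos - seq_len(m)) * miss
  at_hit <- cw - deficit
  before_hit <- c(0, cw[-m]) - deficit
  es_max <- max(at_hit, 0)
  es_min <- min(before_hit, 0)
  if (es_max >= -es_min) {
    list(es = es_max, arg = if (es_max > 0) which.max(at_hit) else 0L)
  } else {
    list(es = es_min, arg = which.min(before_hit))
  }
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' Classic walking-sum enrichment on a correlation-ranked gene list: moving
#' down the ranking, the running sum gains `|r|^p` (normalized by the total
#' hit weight) at set members and loses `1/(N - m)` at non-members; the
#' enrichment score ES is the signed extremum.  The null distribution comes
#' from `n_perm` random gene-label assignments of the same set size under a
#' fixed seed; NES divides ES by the mean |null ES| of matching sign, and
#' the permutation p-value is `(1 + #{null at least as extreme, same sign})
#' / (1 + #{null of that sign})`, BH-adjusted across sets.
#'
#' @param ranking a `correlation_ranking` (or data.frame with `gene`, `r`);
#'   ties in r are broken by symbol for determinism.
#' @param sets a `gene_set_collection` (or named list of gene vectors).
#' @param weight_p hit-weight exponent on |r| (default 1; 0 = unweighted).
#' @param n_perm number of permutations (default 1000; 0 reports ES only).
#' @param seed RNG seed for the permutation null.
#' @param min_size,max_size set-size bounds on ranked members (defaults 5
#'   and half the ranked genes); sets outside are skipped with a warning.
#' @return data.frame `set`, `size`, `ES`, `NES`, `p_perm`, `q`,
#'   `leading_edge` (comma-separated).
#' @export
preranked_gsea <- function(ranking, sets, weight_p = 1, n_perm = 1000,
                           seed = 1, min_size = 5, max_size = NULL) {
  stopifnot(is.data.frame(ranking), all(c("gene", "r") %in% colnames(ranking)))
  ranking <- ranking[!is.na(ranking$r), , drop = FALSE]
  ranking <- ranking[order(-ranking$r, ranking$gene), , drop = FALSE]
  genes <- toupper(ranking$gene)
  rvec <- ranking$r
  N <- length(genes)
  if (is.null(max_size)) max_size <- floor(N / 2)
  absr <- abs(rvec)
  set.seed(seed)
  rows <- list()
  for (nm in names(sets)) {
    pos <- which(genes %in% toupper(sets[[nm]]))
    m <- length(pos)
    if (m < min_size || m > max_size) {
      warning("set '", nm, "' has ", m, " ranked genes (outside [",
              min_size, ", ", max_size, "]); skipped")
      next
    }
    obs <- .gsea_es(pos, absr, weight_p, N)
    es <- obs$es
    nes <- NA_real_; pp <- NA_real_
    if (n_perm > 0L) {
      null_es <- vapply(seq_len(n_perm), function(i) {
        .gsea_es(sort(sample.int(N, m)), absr, weight_p, N)$es
      }, numeric(1))
      same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      if (length(same)) {
        nes <- es / mean(abs(same))
        pp <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      }
    }
    lead <- if (obs$arg > 0L) {
      if (es >= 0) genes[pos[seq_len(obs$arg)]]
      else genes[pos[seq(obs$arg, m)]]
    } else character(0)
    rows[[nm]] <- data.frame(set = nm, size = m, ES = es, NES = nes,
                             p_perm = pp,
                             leading_edge = paste(lead, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p_perm = numeric(0), q = numeric(0),
                      leading_edge = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p_perm)
  out[, c("set", "size", "ES", "NES", "p_perm", "q", "leading_edge")]
}
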