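#' Per-sample zinc signature score
#'
#' The score of a sample is the arithmetic mean of the measured signature
#' genes' normalized log2 expression values in that sample (equal weights).
#' Scores are comparable only within one dataset/platform; cross-dataset
#' comparisons go through fold changes against each dataset's own controls.
#'
#' @param dataset a normalized `zinc_dataset` (log2 intensity or log2-CPM;
#'   counts must be converted first, see [counts_to_logcpm()]).
#' @param signature character vector of signature gene symbols.
#' @param min_fraction_present minimum fraction of signature genes that must
#'   be measured in the dataset (default 0.5); below it an error lists the
#'   missing genes.
#' @return Named numeric vector of per-sample scores.
#' @export
compute_score <- function(dataset, signature, min_fraction_present = 0.5) {
  stopifnot(inherits(dataset, "zinc_dataset"), length(signature) >= 1L)
  if (dataset$platform == "counts")
    stop("counts must be normalized to log2-CPM before scoring; see counts_to_logcpm()")
  signature <- unique(toupper(signature))
  rn <- rownames(dataset$values)
  present <- signature[signature %in% rn]
  present <- present[rowSums(!is.na(dataset$values[present, , drop = FALSE])) > 0L]
  need <- ceiling(min_fraction_present * length(signature))
  if (length(present) < need)
    stop("too few signature genes measured (", length(present), " of ",
         length(signature), "); missing: ",
         paste(setdiff(signature, present), collapse = ", "))
  colMeans(dataset$values[present, , drop = FALSE], na.rm = TRUE)
}

#' Signature fold change versus controls
#'
#' Per signature gene, LOG2FC = mean(disease log2) - mean(control log2); the
#' score-level LOG2FC is the same contrast on the per-sample scores.
#'
#' @param dataset normalized `zinc_dataset` with two group levels.
#' @param signature signature gene symbols.
#' @param scores per-sample scores (computed via [compute_score()] when
#'   `NULL`).
#' @param control control/healthy group level (inferred when `NULL`).
#' @return List: `score_log2fc` (scalar), `per_gene` (data.frame `gene`,
#'   `log2fc`).
#' @export
score_log2fc <- function(dataset, signature, scores = NULL, control = NULL) {
  control <- .control_level(dataset$groups, control)
  if (is.null(scores)) scores <- compute_score(dataset, signature)
  grp <- dataset$groups[names(scores)]
  ctl <- grp == control
  if (!any(ctl)) stop("missing control group '", control, "'")
  if (all(ctl)) stop("missing non-control group")
  signature <- unique(toupper(signature))
  present <- intersect(signature, rownames(dataset$values))
  m <- dataset$values[present, , drop = FALSE]
  grp_m <- dataset$groups[colnames(m)] == control
  per_gene <- data.frame(
    gene = present,
    log2fc = rowMeans(m[, !grp_m, drop = FALSE], na.rm = TRUE) -
             rowMeans(m[, grp_m, drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  list(score_log2fc = mean(scores[!ctl]) - mean(scores[ctl]),
       per_gene = per_gene)
}

#' Quartile stratification of signature scores
#'
#' Samples are sorted descending by score (ties broken by sample id
#' ascending); the sample at descending rank r is assigned quartile
#' `floor(4 * (r - 1) / n) + 1`, so quartile 1 holds the highest scores.
#' Quartile sizes differ by at most one.
#'
#' @param scores named numeric vector of per-sample scores (n >= 4).
#' @return Named integer vector of quartile assignments in 1..4.
#' @export
quartile_stratify <- function(scores) {
  n <- length(scores)
  if (n < 4L) stop("quartile stratification requires at least 4 samples")
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  o <- order(-scores, ids)
  q <- integer(n)
  q[o] <- as.integer(floor(4 * (seq_len(n) - 1) / n) + 1)
  stats::setNames(q, ids)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Unpaired two-sample rank-sum comparison.  The two-sided p-value is exact
#' by enumeration of all rank assignments when `n_a + n_b <= 12` (ties
#' handled through average ranks), and a normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return List with `U` (Mann-Whitney U for sample `a`) and `p` (two-sided).
#' @export
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= 12L) {
    combs <- utils::combn(n, na)
    Us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  } else {
    tie <- table(r)
    tiecor <- sum(tie^3 - tie) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tiecor)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, (abs(U - mu) - 0.5)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    }
  }
  list(U = U, p = p)
}

#' Correlate signature scores with clinical covariates
#'
#' Pearson correlation between the per-sample score and each covariate,
#' missing covariate values dropped pairwise; p-values from the t transform
#' on n - 2 degrees of freedom.  Covariates with fewer than 3 paired values
#' or zero variance are reported as missing with a warning.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param covariates data.frame of numeric covariates, rownames = sample ids.
#' @param names covariate columns to test (default: all).
#' @return data.frame `covariate`, `n`, `r`, `p`.
#' @export
correlate_covariates <- function(scores, covariates, names = colnames(covariates)) {
  stopifnot(is.data.frame(covariates))
  covariates <- covariates[base::names(scores), , drop = FALSE]
  rows <- lapply(names, function(nm) {
    y <- covariates[[nm]]
    ok <- !is.na(scores) & !is.na(y)
    if (sum(ok) < 3L) {
      warning("covariate '", nm, "' has fewer than 3 paired values")
      return(data.frame(covariate = nm, n = sum(ok), r = NA_real_, p = NA_real_))
    }
    if (stats::var(y[ok]) == 0 || stats::var(scores[ok]) == 0) {
      warning("covariate '", nm, "' has zero variance; correlation undefined")
      return(data.frame(covariate = nm, n = sum(ok), r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(scores[ok], y[ok], method = "pearson")
    data.frame(covariate = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score a cohort with a zinc signature
#'
#' Computes per-sample signature scores, quartile assignments, the
#' disease-versus-control fold change of the score and of every signature
#' gene, a rank-sum comparison of top versus bottom score quartile, and
#' Pearson correlations with any per-sample covariates.
#'
#' @param dataset normalized `zinc_dataset` for the cohort.
#' @param signature a `zinc_signature` object or character vector of genes.
#' @param control control/healthy group level; `NA` skips the group contrast
#'   (scores and quartiles only), `NULL` infers it from the labels.
#' @param min_fraction_present passed to [compute_score()].
#' @return An object of class `scored_cohort`: list with `sample`, `score`,
#'   `quartile`, `group`, `log2fc` (score + per-gene), `quartile_test`
#'   (top vs bottom quartile rank-sum on scores), `correlations`,
#'   `signature`, `dataset_id`.
#' @export
score_cohort <- function(dataset, signature, control = NULL,
                         min_fraction_present = 0.5) {
  genes <- if (inherits(signature, "zinc_signature")) signature$genes
           else unique(toupper(signature))
  scores <- compute_score(dataset, genes, min_fraction_present)
  quart <- if (length(scores) >= 4L) quartile_stratify(scores)
           else stats::setNames(rep(NA_integer_, length(scores)), names(scores))
  lfc <- NULL
  skip_contrast <- length(control) == 1L && is.na(control)
  if (!skip_contrast && length(unique(dataset$groups)) == 2L)
    lfc <- score_log2fc(dataset, genes, scores = scores, control = control)
  qtest <- NULL
  if (all(!is.na(quart)) && sum(quart == 1L) >= 2L && sum(quart == 4L) >= 2L)
    qtest <- rank_sum_test(scores[quart == 1L], scores[quart == 4L])
  corr <- NULL
  if (!is.null(dataset$covariates) && ncol(dataset$covariates) > 0L)
    corr <- correlate_covariates(scores, dataset$covariates)
  structure(list(sample = names(scores), score = scores, quartile = quart,
                 group = dataset$groups[names(scores)],
                 log2fc = lfc, quartile_test = qtest, correlations = corr,
                 signature = genes, dataset_id = dataset$dataset_id),
            class = "scored_cohort")
}

#' @export
print.scored_cohort <- function(x, ...) {
  cat(sprintf("<scored_cohort> %s: %d samples scored on %d signature genes\n",
              x$dataset_id, length(x$score), length(x$signature)))
  cat(sprintf("  score range: [%.3f, %.3f]\n", min(x$score), max(x$score)))
  if (!is.null(x$log2fc))
    cat(sprintf("  score LOG2FC vs controls: %.3f\n", x$log2fc$score_log2fc))
  invisible(x)
}

#' @export
summary.scored_cohort <- function(object, ...) {
  print(object)
  if (!is.null(object$log2fc)) {
    cat("Per-gene LOG2FC:\n")
    print(object$log2fc$per_gene, row.names = FALSE, digits = 3)
  }
  if (!is.null(object$quartile_test))
    cat(sprintf("Top vs bottom quartile rank-sum: U = %.1f, p = %.3g\n",
                object$quartile_test$U, object$quartile_test$p))
  if (!is.null(object$correlations)) {
    cat("Covariate correlations:\n")
    print(object$correlations, row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Score new data with a derived signature
#'
#' @param object a `zinc_signature`.
#' @param dataset a normalized `zinc_dataset` to score.
#' @param ... passed to [score_cohort()].
#' @return A `scored_cohort`.
#' @export
predict.zinc_signature <- function(object, dataset, ...) {
  score_cohort(dataset, object, ...)
}
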