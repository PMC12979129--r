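#' Log2-transform an intensity dataset when on linear scale
#'
#' Array matrices arrive on either linear or log scale; a matrix whose
#' maximum exceeds `linear_threshold` (default 50) is treated as linear and
#' log2-transformed, otherwise passed through unchanged.  The decision is
#' recorded in the returned object (`$log_transformed`).
#'
#' @param dataset an intensity-platform `zinc_dataset`.
#' @param offset added before taking logs; must make all values positive on
#'   a linear-scale matrix (default 0, i.e. an error on non-positive values).
#' @param linear_threshold maximum-value heuristic separating linear from
#'   already-logged matrices.
#' @return The dataset with `log_scale = TRUE` and a `log_transformed` flag.
#' @export
log_transform <- function(dataset, offset = 0, linear_threshold = 50) {
  stopifnot(inherits(dataset, "zinc_dataset"))
  if (dataset$platform != "intensity")
    stop("log_transform applies to intensity datasets; use counts_to_logcpm for counts")
  v <- dataset$values
  mx <- suppressWarnings(max(v, na.rm = TRUE))
  if (is.finite(mx) && mx > linear_threshold) {
    v <- v + offset
    if (any(v <= 0, na.rm = TRUE))
      stop("non-positive values on a linear-scale matrix; configure a positive `offset`")
    dataset$values <- log2(v)
    dataset$log_transformed <- TRUE
  } else {
    dataset$log_transformed <- FALSE
  }
  dataset$log_scale <- TRUE
  dataset
}

#' Quantile-normalize a log-scale matrix
#'
#' Forces every sample (column) onto a common distribution: the across-sample
#' mean of sorted values.  Ties within a sample receive the mean of the
#' quantile values they span.  Missing values are permitted and left in
#' place; a column with missing values is mapped through an interpolated
#' reference of matching length.
#'
#' @param x numeric matrix (genes x samples), log2 scale.
#' @return The normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  S <- ncol(x)
  if (S <= 1L) return(x)
  G <- nrow(x)
  if (G == 0L) return(x)
  grid <- function(n) if (n == 1L) 0.5 else seq(0, 1, length.out = n)
  sorted <- lapply(seq_len(S), function(j) sort(x[, j][!is.na(x[, j])]))
  if (any(lengths(sorted) == 0L)) stop("a sample has no non-missing values")
  ref_cols <- vapply(sorted, function(v) {
    if (length(v) == G) v
    else stats::approx(grid(length(v)), v, grid(G), rule = 2)$y
  }, numeric(G))
  ref <- rowMeans(ref_cols)
  out <- x
  for (j in seq_len(S)) {
    ok <- !is.na(x[, j])
    n <- sum(ok)
    refj <- if (n == G) ref else stats::approx(grid(G), ref, grid(n), rule = 2)$y
    v <- x[ok, j]
    o <- order(v)
    res <- numeric(n)
    res[o] <- refj
    # tie groups occupy contiguous sorted positions; average the spanned quantiles
    res <- stats::ave(res, factor(v), FUN = mean)
    out[ok, j] <- res
  }
  out
}

#' Normalize an intensity dataset (log transform + quantile normalization)
#'
#' @param dataset intensity-platform `zinc_dataset`.
#' @param quantile apply [quantile_normalize()] after the log transform
#'   (default `TRUE`).
#' @param offset,linear_threshold passed to [log_transform()].
#' @return The normalized dataset.
#' @export
normalize_dataset <- function(dataset, quantile = TRUE, offset = 0,
                              linear_threshold = 50) {
  dataset <- log_transform(dataset, offset = offset,
                           linear_threshold = linear_threshold)
  if (quantile) dataset$values <- quantile_normalize(dataset$values)
  dataset
}

#' Convert counts to filtered log2 counts-per-million
#'
#' CPM = count / library size x 1e6.  Genes are kept iff CPM >= `min_cpm` in
#' at least `min_samples` samples (default: the size of the smaller group);
#' kept values become `log2(CPM + 0.5)`.
#'
#' @param dataset counts-platform `zinc_dataset`.
#' @param min_cpm CPM threshold for the expression filter.
#' @param min_samples number of samples that must pass `min_cpm`; defaults
#'   to the smaller group size.
#' @return A list: `dataset` (intensity platform, log2 scale) and
#'   `filtered_genes` (symbols removed by the filter).
#' @export
counts_to_logcpm <- function(dataset, min_cpm = 1, min_samples = NULL) {
  stopifnot(inherits(dataset, "zinc_dataset"))
  if (dataset$platform != "counts") stop("counts_to_logcpm requires a counts dataset")
  counts <- dataset$values
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero library for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(min_samples)) min_samples <- min(table(dataset$groups))
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  filtered <- rownames(counts)[!keep]
  dataset$values <- log2(cpm[keep, , drop = FALSE] + 0.5)
  dataset$platform <- "intensity"
  dataset$log_scale <- TRUE
  dataset$logcpm <- TRUE
  list(dataset = dataset, filtered_genes = filtered)
}
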