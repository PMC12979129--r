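#' Construct an expression dataset
#'
#' The unit of analysis for signature derivation and scoring: one study's
#' gene-by-sample matrix together with its platform kind, two-group labels,
#' batch label, and optional per-sample numeric covariates.  Gene symbols are
#' upper-cased HGNC-style symbols; a gene that was not measured in a study is
#' simply absent from its matrix (intensity matrices may additionally carry
#' `NA` cells, count matrices may not).
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param platform `"intensity"` (microarray-like, possibly linear scale) or
#'   `"counts"` (non-negative integer RNA-seq counts).
#' @param groups named character vector or factor mapping every sample id to
#'   its group label (e.g. treated/control, disease/healthy).
#' @param dataset_id short identifier used in reports and vote tables.
#' @param batch optional named character vector of batch labels; defaults to
#'   `dataset_id` for every sample.
#' @param covariates optional data.frame of numeric per-sample covariates,
#'   rownames = sample ids (e.g. AST, ALB, INR).
#' @param log_scale logical; `TRUE` once values are on the log2 scale.
#' @return An object of class `zinc_dataset`.
#' @seealso [read_expression_matrix()], [log_transform()], [counts_to_logcpm()]
#' @export
expression_dataset <- function(values, platform = c("intensity", "counts"),
                               groups, dataset_id = "dataset",
                               batch = NULL, covariates = NULL,
                               log_scale = FALSE) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols after harmonization: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (platform == "counts") {
    if (anyNA(values)) stop("counts matrices may not contain missing values")
    if (any(values < 0) || any(abs(values - round(values)) > 1e-8))
      stop("counts platform requires non-negative integer values")
  } else {
    if (any(is.infinite(values))) stop("intensity values must be finite or NA")
  }
  samples <- colnames(values)
  groups <- stats::setNames(as.character(groups), names(groups))
  if (is.null(names(groups))) {
    if (length(groups) != length(samples))
      stop("unnamed `groups` must have one label per sample")
    names(groups) <- samples
  }
  missing_grp <- setdiff(samples, names(groups))
  if (length(missing_grp))
    stop("missing group label for sample(s): ", paste(missing_grp, collapse = ", "))
  groups <- groups[samples]
  if (anyNA(groups)) stop("group labels may not be NA")
  if (is.null(batch)) batch <- stats::setNames(rep(dataset_id, length(samples)), samples)
  if (is.null(names(batch))) {
    if (length(batch) == 1L) batch <- stats::setNames(rep(batch, length(samples)), samples)
    else names(batch) <- samples
  }
  batch <- stats::setNames(as.character(batch[samples]), samples)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    miss <- setdiff(samples, rownames(covariates))
    if (length(miss))
      stop("covariates missing for sample(s): ", paste(miss, collapse = ", "))
    covariates <- covariates[samples, , drop = FALSE]
  }
  structure(list(dataset_id = dataset_id, platform = platform,
                 values = values, groups = groups, batch = batch,
                 covariates = covariates, log_scale = isTRUE(log_scale)),
            class = "zinc_dataset")
}

#' @export
print.zinc_dataset <- function(x, ...) {
  cat(sprintf("<zinc_dataset> %s: %d genes x %d samples (%s%s)\n",
              x$dataset_id, nrow(x$values), ncol(x$values), x$platform,
              if (x$log_scale) ", log2 scale" else ""))
  tab <- table(x$groups)
  cat("  groups: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(colnames(x$covariates), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.zinc_dataset <- function(x) dim(x$values)

#' Read an expression matrix with sample metadata
#'
#' Expects a tab-separated matrix whose first column holds gene symbols
#' (header `gene`) with one column per sample, plus a metadata TSV with
#' columns `sample`, `group`, optional `batch`, and any further numeric
#' columns treated as covariates.  Duplicate gene-symbol rows are collapsed
#' to the row with the highest mean value; symbols are upper-cased.
#'
#' @param path path to the expression TSV.
#' @param platform `"intensity"` or `"counts"`.
#' @param metadata_path path to the sample metadata TSV.
#' @param dataset_id identifier for the resulting dataset; defaults to the
#'   file name without extension.
#' @return A [expression_dataset()] object.
#' @export
read_expression_matrix <- function(path, platform = c("intensity", "counts"),
                                   metadata_path, dataset_id = NULL) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (nrow(tab) == 0L) stop("no data rows in ", path)
  genes <- toupper(as.character(tab[[1L]]))
  num <- tab[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    v <- num[[j]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                     v[bad[1L]], bad[1L], colnames(num)[j], path))
      num[[j]] <- conv
    }
  }
  mat <- as.matrix(num)
  if (platform == "counts" && any(abs(mat - round(mat)) > 1e-8, na.rm = TRUE))
    stop("counts platform with fractional values in ", path)
  rownames(mat) <- genes
  # collapse duplicate symbols: keep the row with the highest mean value
  if (anyDuplicated(genes)) {
    means <- rowMeans(mat, na.rm = TRUE)
    ord <- order(genes, -means)
    mat <- mat[ord, , drop = FALSE]
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
  }
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% colnames(meta)))
    stop("metadata must contain columns 'sample' and 'group'")
  missing <- setdiff(colnames(mat), meta$sample)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(mat), meta$sample), , drop = FALSE]
  groups <- stats::setNames(meta$group, meta$sample)
  batch <- if ("batch" %in% colnames(meta)) stats::setNames(meta$batch, meta$sample) else NULL
  covar_cols <- setdiff(colnames(meta), c("sample", "group", "batch"))
  covar_cols <- covar_cols[vapply(meta[covar_cols], is.numeric, logical(1))]
  covariates <- if (length(covar_cols)) {
    cv <- meta[, covar_cols, drop = FALSE]
    rownames(cv) <- meta$sample
    cv
  } else NULL
  if (is.null(dataset_id)) dataset_id <- sub("\\.[^.]*$", "", basename(path))
  expression_dataset(mat, platform, groups, dataset_id = dataset_id,
                     batch = batch, covariates = covariates)
}

#' Write an expression dataset back to TSV
#'
#' Numeric values are written with 17 significant digits so that a
#' read/write/read cycle reproduces the matrix bit-identically.
#'
#' @param dataset a `zinc_dataset`.
#' @param path output path for the matrix TSV.
#' @param metadata_path optional output path for the metadata TSV.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path, metadata_path = NULL) {
  vals <- dataset$values
  fmt <- matrix(vapply(vals, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1)), nrow = nrow(vals))
  out <- cbind(gene = rownames(vals), as.data.frame(fmt, stringsAsFactors = FALSE))
  colnames(out) <- c("gene", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample = colnames(vals),
                       group = unname(dataset$groups),
                       batch = unname(dataset$batch),
                       stringsAsFactors = FALSE)
    if (!is.null(dataset$covariates)) meta <- cbind(meta, dataset$covariates)
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#' Symbols are upper-cased and de-duplicated within each set.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors of class `gene_set_collection`,
#'   with per-set descriptions in `attr(, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_sets(list()))
  }
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    genes <- unique(toupper(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop(sprintf("GMT line %d defines an empty set", i))
    sets[[f[1L]]] <- genes
    desc[f[1L]] <- f[2L]
  }
  gene_sets(sets, descriptions = desc)
}

#' Construct a gene set collection
#'
#' @param sets named list of character vectors of gene symbols.
#' @param descriptions optional named character vector of set descriptions.
#' @return A `gene_set_collection` object.
#' @export
gene_sets <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(g) unique(toupper(g)))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' Write a gene set collection to GMT
#'
#' @param sets a `gene_set_collection` or named list of gene vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && !is.na(desc[nm])) desc[nm] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)\n", length(x)))
  for (nm in utils::head(names(x), 10))
    cat(sprintf("  %s: %d genes\n", nm, length(x[[nm]])))
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Harmonize gene symbols across datasets
#'
#' Computes the union of gene symbols across datasets and, for every union
#' gene, the set of dataset ids in which it was measured (present in the
#' matrix with at least one non-missing value).  Datasets are not subset to
#' the intersection; missingness stays representable downstream.
#'
#' @param datasets list of `zinc_dataset` objects.
#' @return A list with elements `datasets` (unchanged input), `genes`
#'   (sorted union of symbols) and `measured_in` (named list: gene ->
#'   character vector of dataset ids).
#' @export
harmonize_genes <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  ids <- vapply(datasets, function(d) d$dataset_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dataset ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  per <- lapply(datasets, function(d) {
    rn <- rownames(d$values)
    rn[rowSums(!is.na(d$values)) > 0L]
  })
  genes <- sort(unique(unlist(per)))
  measured_in <- stats::setNames(vector("list", length(genes)), genes)
  for (i in seq_along(datasets)) {
    for (g in per[[i]]) measured_in[[g]] <- c(measured_in[[g]], ids[[i]])
  }
  list(datasets = datasets, genes = genes, measured_in = measured_in)
}
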