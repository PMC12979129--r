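#' @keywords internal
.control_level <- function(groups, control = NULL) {
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L)
    stop("exactly two group levels required, got: ", paste(lv, collapse = ", "))
  if (!is.null(control)) {
    if (!control %in% lv) stop("control level '", control, "' not among: ",
                               paste(lv, collapse = ", "))
    return(control)
  }
  known <- c("control", "mock", "healthy", "normal", "untreated", "vehicle")
  hit <- lv[tolower(lv) %in% known]
  if (length(hit) == 1L) return(hit)
  stop("cannot infer the control group from levels ",
       paste(lv, collapse = ", "), "; specify `control`")
}

# per-gene group means, pooled variance and residual df from a log2 matrix
.group_stats <- function(mat, groups, control) {
  g2 <- colnames(mat)[groups[colnames(mat)] == control]
  g1 <- setdiff(colnames(mat), g2)
  stats_for <- function(cols) {
    m <- mat[, cols, drop = FALSE]
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    ss <- rowSums((m - mu)^2, na.rm = TRUE)
    list(n = n, mu = mu, ss = ss)
  }
  a <- stats_for(g1); b <- stats_for(g2)
  d <- a$n + b$n - 2L
  s2 <- ifelse(d > 0, (a$ss + b$ss) / pmax(d, 1L), NA_real_)
  measured <- a$n >= 2L & b$n >= 2L
  list(n1 = a$n, n2 = b$n, mu1 = a$mu, mu2 = b$mu, d = d, s2 = s2,
       measured = measured)
}

#' @keywords internal
.trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Fit the variance-moderation prior
#'
#' Per-gene residual variances with their degrees of freedom are fit to a
#' scaled inverse-chi-square prior by moment matching on the log scale
#' (Smyth-2004 style): the prior degrees of freedom `d0` come from inverting
#' the trigamma equation for the excess spread of `log s_g^2`, and the prior
#' variance `s0_sq` from the location.  If the excess spread is non-positive
#' the prior is degenerate: `d0 = Inf` and `s0_sq` equals the mean variance.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param groups named group labels covering the columns of `mat`.
#' @param control which group level is the control (inferred when `NULL`).
#' @return A `moderation_params` list with elements `d0` and `s0_sq`.
#' @references Smyth, G.K. (2004) Linear models and empirical Bayes methods
#'   for assessing differential expression in microarray experiments.
#' @export
fit_moderation <- function(mat, groups, control = NULL) {
  control <- .control_level(groups, control)
  st <- .group_stats(mat, groups, control)
  ok <- st$measured & st$d > 0 & is.finite(st$s2) & st$s2 > 0
  if (sum(ok) < 10L) stop("insufficient genes to estimate prior")
  s2 <- st$s2[ok]; d <- st$d[ok]
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(d / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_params")
}

#' @export
print.moderation_params <- function(x, ...) {
  cat(sprintf("<moderation_params> d0 = %s, s0_sq = %.4g\n",
              format(x$d0, digits = 4), x$s0_sq))
  invisible(x)
}

#' Moderated two-sample t-test
#'
#' For every gene the posterior variance
#' `s_tilde^2 = (d0 * s0_sq + d_g * s_g^2) / (d0 + d_g)` shrinks the pooled
#' residual variance toward the prior; the statistic
#' `t = (mean_treated - mean_control) / (s_tilde * sqrt(1/n1 + 1/n2))` is
#' referred to a t distribution on `d0 + d_g` degrees of freedom
#' (standard-normal limit when `d0` is infinite).  `d0 = 0` recovers the
#' ordinary pooled-variance t-test.  A gene with fewer than two measured
#' samples in either group is flagged unmeasured and excluded from calls.
#'
#' @param mat log2 expression matrix (genes x samples).
#' @param groups named group labels for the columns of `mat`.
#' @param params a `moderation_params` object (see [fit_moderation()]).
#' @param control control group level (inferred when `NULL`).
#' @return data.frame with columns `gene`, `log2fc` (treated minus control),
#'   `t`, `p` (two-sided), `measured`.
#' @export
moderated_t_test <- function(mat, groups, params, control = NULL) {
  stopifnot(inherits(params, "moderation_params"))
  control <- .control_level(groups, control)
  st <- .group_stats(mat, groups, control)
  d0 <- params$d0; s0 <- params$s0_sq
  if (is.finite(d0)) {
    stilde2 <- ifelse(st$d > 0, (d0 * s0 + st$d * st$s2) / (d0 + st$d), s0)
    df <- d0 + st$d
  } else {
    stilde2 <- rep(s0, length(st$d))
    df <- rep(Inf, length(st$d))
  }
  fc <- st$mu1 - st$mu2
  se <- sqrt(stilde2 * (1 / st$n1 + 1 / st$n2))
  t <- fc / se
  t[which(se == 0 & fc == 0)] <- 0
  p <- ifelse(is.finite(df),
              2 * stats::pt(abs(t), df = df, lower.tail = FALSE),
              2 * stats::pnorm(abs(t), lower.tail = FALSE))
  p <- pmax(p, .Machine$double.xmin)
  p <- pmin(p, 1)
  out <- data.frame(gene = rownames(mat), log2fc = unname(fc),
                    t = unname(t), p = unname(p),
                    measured = unname(st$measured),
                    stringsAsFactors = FALSE)
  out$log2fc[!out$measured] <- NA_real_
  out$t[!out$measured] <- NA_real_
  out$p[!out$measured] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, monotone
#' and capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1]; `NA` passes through.
#' @return Vector of adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Threshold-based regulation calls
#'
#' A gene is called up-regulated when its fold change reaches
#' `fold_threshold` (log2fc >= log2(fold_threshold), boundary inclusive) with
#' significance strictly below `alpha`; down-regulation is the mirror call.
#' The significance gate is the raw p-value by default, or the BH-adjusted
#' value when `use_fdr = TRUE`.
#'
#' @param results data.frame from [moderated_t_test()] (columns `log2fc`,
#'   `p`, `measured`; `fdr` added here if absent).
#' @param fold_threshold linear fold-change threshold (default 1.5).
#' @param alpha significance level (default 0.05, strict `<`).
#' @param use_fdr gate on BH-adjusted values instead of raw p.
#' @return `results` with columns `fdr`, `up`, `down` added/updated.
#' @export
call_regulated <- function(results, fold_threshold = 1.5, alpha = 0.05,
                           use_fdr = FALSE) {
  if (is.null(results$fdr)) results$fdr <- bh_adjust(results$p)
  gate <- if (use_fdr) results$fdr else results$p
  lfc <- log2(fold_threshold)
  up <- results$measured & !is.na(gate) & results$log2fc >= lfc & gate < alpha
  down <- results$measured & !is.na(gate) & results$log2fc <= -lfc & gate < alpha
  results$up <- up & !is.na(up)
  results$down <- down & !is.na(down)
  results$up[is.na(results$up)] <- FALSE
  results$down[is.na(results$down)] <- FALSE
  results
}

#' Per-dataset differential expression
#'
#' Runs the platform-appropriate pipeline for one two-group dataset:
#' intensity matrices are log2-transformed (when linear) and
#' quantile-normalized, count matrices are converted to filtered log2-CPM;
#' both are then tested with the moderated t ([fit_moderation()] +
#' [moderated_t_test()]), BH-adjusted, and thresholded into up/down calls.
#'
#' @param dataset a `zinc_dataset`.
#' @param fold_threshold,alpha,use_fdr passed to [call_regulated()].
#' @param quantile quantile-normalize intensity matrices (default `TRUE`).
#' @param control control group level (inferred when `NULL`).
#' @param min_cpm,min_samples count-filter settings, see [counts_to_logcpm()].
#' @param offset log-transform offset for linear-scale intensity data.
#' @return data.frame with columns `gene`, `log2fc`, `t`, `p`, `fdr`, `up`,
#'   `down`, `measured`; attributes `dataset_id`, `params`
#'   (the fitted `moderation_params`) and `filtered_genes` (counts path).
#' @export
run_de <- function(dataset, fold_threshold = 1.5, alpha = 0.05,
                   use_fdr = FALSE, quantile = TRUE, control = NULL,
                   min_cpm = 1, min_samples = NULL, offset = 0) {
  stopifnot(inherits(dataset, "zinc_dataset"))
  filtered <- character(0)
  if (dataset$platform == "counts") {
    conv <- counts_to_logcpm(dataset, min_cpm = min_cpm, min_samples = min_samples)
    work <- conv$dataset
    filtered <- conv$filtered_genes
  } else {
    work <- if (dataset$log_scale) dataset
            else log_transform(dataset, offset = offset)
    if (quantile) work$values <- quantile_normalize(work$values)
  }
  params <- fit_moderation(work$values, work$groups, control = control)
  res <- moderated_t_test(work$values, work$groups, params, control = control)
  res$fdr <- bh_adjust(res$p)
  res <- call_regulated(res, fold_threshold = fold_threshold, alpha = alpha,
                        use_fdr = use_fdr)
  res <- res[, c("gene", "log2fc", "t", "p", "fdr", "up", "down", "measured")]
  attr(res, "dataset_id") <- dataset$dataset_id
  attr(res, "params") <- params
  attr(res, "filtered_genes") <- filtered
  res
}
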