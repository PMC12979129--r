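# independent brute-force oracles used to freeze expected values

# BH step-up from the definition: sort ascending, adj_(i) = min_{j >= i} m/j p_(j)
bh_stepup_brute <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  o <- order(p)
  sorted <- p[o]
  adj <- vapply(seq_len(m), function(i) min(1, min(m / seq(i, m) * sorted[seq(i, m)])),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by exhaustive enumeration of all draws
hyper_upper_brute <- function(k, n_ref, n_universe, n_query) {
  if (n_query == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(n_universe, n_query)
  ref <- seq_len(n_ref)
  mean(apply(draws, 2L, function(d) sum(d %in% ref)) >= k)
}

# ordinary pooled-variance two-sample t-test, coded independently of the package
ordinary_t_brute <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(abs(t), df = n1 + n2 - 2, lower.tail = FALSE))
}

# all permutations of a vector (small n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# small two-group intensity dataset on the log2 scale
make_intensity_dataset <- function(n_genes = 50, n_per_group = 4, shift = 0,
                                   shifted_genes = character(0), sd = 0.3,
                                   id = "TEST", seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  treated <- sprintf("%s_T%d", id, seq_len(n_per_group))
  control <- sprintf("%s_C%d", id, seq_len(n_per_group))
  m <- matrix(stats::rnorm(n_genes * 2 * n_per_group, mean = 8, sd = sd),
              n_genes, 2 * n_per_group, dimnames = list(genes, c(treated, control)))
  if (length(shifted_genes)) m[shifted_genes, treated] <- m[shifted_genes, treated] + shift
  groups <- stats::setNames(rep(c("treated", "control"), each = n_per_group),
                            c(treated, control))
  expression_dataset(m, "intensity", groups, dataset_id = id, log_scale = TRUE)
}

# minimal DE-result data.frame for consensus-level tests
make_de <- function(genes, up = character(0), down = character(0),
                    measured = genes, log2fc = NULL, id = "DS") {
  if (is.null(log2fc)) {
    log2fc <- stats::setNames(rep(0, length(genes)), genes)
    log2fc[up] <- 1; log2fc[down] <- -1
  }
  d <- data.frame(gene = genes,
                  log2fc = unname(log2fc[genes]),
                  t = 0, p = 0.5, fdr = 0.5,
                  up = genes %in% up, down = genes %in% down,
                  measured = genes %in% measured,
                  stringsAsFactors = FALSE)
  d$log2fc[!d$measured] <- NA_real_
  attr(d, "dataset_id") <- id
  d
}
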