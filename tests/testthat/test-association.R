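test_that("batch merging removes per-gene batch offsets", {
  mk <- function(id, shift, seed) {
    set.seed(seed)
    g <- sprintf("G%03d", 1:150)
    s <- sprintf("%s_s%d", id, 1:6)
    m <- matrix(rnorm(150 * 6, 8, 0.5), 150, 6, dimnames = list(g, s)) + shift
    expression_dataset(m, "intensity",
                       stats::setNames(rep("disease", 6), s),
                       dataset_id = id, log_scale = TRUE)
  }
  d1 <- mk("B1", 0, 51)
  set.seed(52); delta <- rnorm(150, 0, 2)
  d2 <- mk("B2", 0, 53)
  d2$values <- d2$values + delta
  merged <- merge_batches(list(d1, d2), min_common = 100)
  expect_identical(sort(unique(unname(merged$batch))), c("B1", "B2"))
  b <- merged$batch
  diffs <- rowMeans(merged$values[, b == "B1"]) - rowMeans(merged$values[, b == "B2"])
  expect_lt(max(abs(diffs)), 1e-10)

  # single batch: output equals the quantile-normalized input
  one <- merge_batches(list(d1), min_common = 100)
  expect_equal(one$values, quantile_normalize(d1$values)[sort(rownames(d1$values)), ],
               tolerance = 1e-12)

  expect_error(merge_batches(list(d1, d2), min_common = 500), "share only")
})

test_that("a gene constant within one batch gets a finite location-only fix", {
  g <- sprintf("G%03d", 1:120)
  mk <- function(id, seed) {
    set.seed(seed)
    s <- sprintf("%s_s%d", id, 1:5)
    expression_dataset(matrix(rnorm(120 * 5, 8), 120, 5, dimnames = list(g, s)),
                       "intensity", stats::setNames(rep("disease", 5), s),
                       dataset_id = id, log_scale = TRUE)
  }
  d1 <- mk("B1", 54); d2 <- mk("B2", 55)
  d1$values["G007", ] <- 3  # zero within-batch variance
  merged <- merge_batches(list(d1, d2), min_common = 100, quantile = FALSE)
  expect_true(all(is.finite(merged$values["G007", ])))
  b <- merged$batch
  expect_equal(mean(merged$values["G007", b == "B1"]),
               mean(merged$values["G007", b == "B2"]), tolerance = 1e-10)
})

test_that("genome-wide correlation ranks a score-identical gene first", {
  co <- simulate_disease_cohort(n_disease = 15, n_healthy = 10, n_genes = 150,
                                seed = 56)
  sc <- compute_score(co$dataset, co$truth$signature)
  ds <- co$dataset
  ds$values <- rbind(ds$values, SCORECOPY = sc, SCORENEG = -sc,
                     FLATGENE = rep(1, length(sc)))
  rk <- correlate_score_genomewide(ds, sc)
  expect_identical(rk$gene[1], "SCORECOPY")
  expect_equal(rk$r[1], 1, tolerance = 1e-12)
  expect_equal(rk$p[1], 0)
  last <- rk[!is.na(rk$rank), ]
  expect_identical(last$gene[nrow(last)], "SCORENEG")
  expect_equal(last$r[nrow(last)], -1, tolerance = 1e-12)
  expect_true(is.na(rk$rank[rk$gene == "FLATGENE"]))
})

test_that("an independent gene rarely correlates strongly at n = 200", {
  set.seed(57)
  hits <- vapply(1:40, function(i) {
    x <- rnorm(200); y <- rnorm(200)
    abs(cor(x, y)) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cross-dataset consensus equals brute-force mean ranks", {
  mk_rank <- function(genes, rvals, id) {
    out <- data.frame(gene = genes, r = rvals, p = 0.5, n = 10,
                      stringsAsFactors = FALSE)
    ord <- order(-out$r, out$gene)
    out <- out[ord, ]
    out$rank <- seq_len(nrow(out))
    attr(out, "dataset_id") <- id
    class(out) <- c("correlation_ranking", "data.frame")
    out
  }
  set.seed(58)
  genes <- sprintf("G%02d", 1:30)
  r1 <- mk_rank(genes, rnorm(30), "A")
  r2 <- mk_rank(genes, rnorm(30), "B")
  top <- cross_dataset_top(list(r1, r2), k = 10)
  mean_rank_brute <- sapply(genes, function(g)
    (r1$rank[r1$gene == g] + r2$rank[r2$gene == g]) / 2)
  expected <- names(sort(mean_rank_brute))[1:10]
  expect_identical(top$gene, expected)

  ident <- cross_dataset_top(list(r1, r1), k = 5)
  expect_identical(ident$gene, r1$gene[1:5])

  expect_warning(cross_dataset_top(list(r1, r2), k = 100), "truncating")
})

test_that("enrichment score matches hand-walked boundary cases", {
  ranking <- data.frame(gene = c("A", "B", "C", "D"), r = c(0.9, 0.5, -0.2, -0.8))
  top <- gene_sets(list(TOP = c("A", "B"), BOTTOM = c("C", "D")))
  res <- preranked_gsea(ranking, top, weight_p = 0, n_perm = 0,
                        min_size = 1, max_size = 4)
  expect_equal(res$ES[res$set == "TOP"], 1.0, tolerance = 1e-12)
  expect_equal(res$ES[res$set == "BOTTOM"], -1.0, tolerance = 1e-12)
  expect_true(all(is.na(res$NES)))  # n_perm = 0 -> ES only
})

test_that("enrichment is reproducible, monotone-invariant at p = 0, and matches fgsea", {
  set.seed(59)
  genes <- sprintf("G%03d", 1:200)
  ranking <- data.frame(gene = genes, r = sort(rnorm(200), decreasing = TRUE))
  sets <- gene_sets(list(S1 = sample(genes, 15), S2 = sample(genes, 25)))
  a <- preranked_gsea(ranking, sets, n_perm = 200, seed = 7)
  b <- preranked_gsea(ranking, sets, n_perm = 200, seed = 7)
  expect_identical(a, b)

  # strictly monotone transform of r leaves the unweighted ES unchanged
  warped <- ranking; warped$r <- tanh(ranking$r) * 3
  e1 <- preranked_gsea(ranking, sets, weight_p = 0, n_perm = 0)
  e2 <- preranked_gsea(warped, sets, weight_p = 0, n_perm = 0)
  expect_equal(e1$ES, e2$ES, tolerance = 1e-12)

  # independent implementation of the weighted walking sum
  st <- stats::setNames(ranking$r, ranking$gene)
  for (nm in names(sets)) {
    ours <- preranked_gsea(ranking, sets[nm], n_perm = 0)$ES
    ref <- fgsea::calcGseaStat(st, selectedStats = which(genes %in% sets[[nm]]),
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }

  # sets outside the size bounds are skipped with a warning
  expect_warning(
    skipped <- preranked_gsea(ranking, gene_sets(list(TINY = genes[1:2])), n_perm = 0),
    "skipped")
  expect_equal(nrow(skipped), 0L)
})

test_that("a planted module enriches positively with a small permutation p", {
  co <- simulate_disease_cohort(seed = 60)
  sc <- compute_score(co$dataset, co$truth$signature)
  rk <- correlate_score_genomewide(co$dataset, sc)
  en <- preranked_gsea(rk, gene_sets(list(MODULE = co$truth$module_genes)),
                       n_perm = 500, seed = 8)
  expect_gt(en$NES, 0)
  expect_lt(en$p_perm, 0.05)
  expect_true(all(strsplit(en$leading_edge, ",")[[1]] %in% co$truth$module_genes))
})
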