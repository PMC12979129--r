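groups8 <- stats::setNames(rep(c("treated", "control"), each = 4), paste0("s", 1:8))

random_log2_matrix <- function(n_genes, seed, sd = 0.5) {
  set.seed(seed)
  matrix(rnorm(n_genes * 8, 8, sd), n_genes, 8,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)), names(groups8)))
}

test_that("moderated t with d0 = 0 equals the ordinary pooled t", {
  m <- random_log2_matrix(100, seed = 21)
  params <- structure(list(d0 = 0, s0_sq = 1), class = "moderation_params")
  res <- moderated_t_test(m, groups8, params)
  for (i in c(1, 17, 60, 100)) {
    o <- ordinary_t_brute(m[i, 1:4], m[i, 5:8])
    expect_equal(res$t[i], o$t, tolerance = 1e-10)
    expect_equal(res$p[i], o$p, tolerance = 1e-10)
  }
})

test_that("moderated t with d0 = Inf uses the prior variance exactly", {
  m <- random_log2_matrix(50, seed = 22)
  params <- structure(list(d0 = Inf, s0_sq = 0.04), class = "moderation_params")
  res <- moderated_t_test(m, groups8, params)
  fc <- rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])
  expect_equal(res$t, unname(fc / sqrt(0.04 * (1 / 4 + 1 / 4))), tolerance = 1e-12)
  # normal reference in the infinite-df limit
  expect_equal(res$p, unname(2 * pnorm(abs(res$t), lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("identical group means give t = 0, p = 1", {
  m <- random_log2_matrix(20, seed = 23)
  m[, 5:8] <- m[, 1:4]  # mirror the groups
  params <- fit_moderation(m, groups8)
  res <- moderated_t_test(m, groups8, params)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
})

test_that("moderation prior recovery: equal variances give large d0, mixtures small", {
  m <- random_log2_matrix(2000, seed = 24, sd = 0.3)
  p_eq <- fit_moderation(m, groups8)
  expect_gte(p_eq$d0, 20)
  expect_equal(p_eq$s0_sq, 0.09, tolerance = 0.3)

  set.seed(25)
  sds <- sample(c(0.1, 1.5), 2000, replace = TRUE, prob = c(0.7, 0.3))
  mh <- matrix(rnorm(2000 * 8, 8, sds), 2000, 8,
               dimnames = dimnames(m))
  p_mix <- fit_moderation(mh, groups8)
  expect_true(is.finite(p_mix$d0))
  expect_lt(p_mix$d0, 20)

  tiny <- random_log2_matrix(5, seed = 26)
  expect_error(fit_moderation(tiny, groups8), "insufficient genes")
})

test_that("moderation prior and statistics agree with limma", {
  m <- random_log2_matrix(500, seed = 27)
  set.seed(28)
  m <- m * rep(runif(500, 0.5, 2), 8)  # heterogeneous variances
  params <- fit_moderation(m, groups8)
  design <- cbind(1, rep(c(1, 0), each = 4))
  fit <- limma::lmFit(m, design)
  fit <- limma::eBayes(fit)
  expect_equal(params$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(params$s0_sq, fit$s2.prior, tolerance = 1e-6)
  res <- moderated_t_test(m, groups8, params)
  expect_equal(res$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4), tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.05, 0.01)), c(0.05, 0.02), tolerance = 1e-12)
  expect_identical(bh_adjust(0.3), 0.3)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(29)
  for (m in 1:8) {
    p <- runif(m)
    expect_equal(bh_adjust(p), bh_stepup_brute(p), tolerance = 1e-12)
  }
})

test_that("regulation calls respect the fold and significance boundaries", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(log2(1.5), 0.58, 1, -log2(1.5)),
                    t = 1, p = c(0.049, 0.001, 0.05, 0.01),
                    measured = TRUE)
  out <- call_regulated(res)
  expect_identical(out$up, c(TRUE, FALSE, FALSE, FALSE))   # >= on fold, < on p
  expect_identical(out$down, c(FALSE, FALSE, FALSE, TRUE))
  expect_false(any(out$up & out$down))
})

test_that("unmeasured genes are excluded from statistics and calls", {
  m <- random_log2_matrix(30, seed = 30)
  m[5, 1:3] <- NA  # one treated value left -> unmeasured
  params <- fit_moderation(m, groups8)
  res <- call_regulated(moderated_t_test(m, groups8, params))
  expect_false(res$measured[5])
  expect_true(is.na(res$p[5]))
  expect_false(res$up[5] || res$down[5])
})

test_that("null raw p-values are calibrated near the nominal level", {
  rates <- vapply(1:5, function(s) {
    m <- random_log2_matrix(1500, seed = 400 + s, sd = 0.4)
    params <- fit_moderation(m, groups8)
    res <- moderated_t_test(m, groups8, params)
    mean(res$p < 0.05)
  }, numeric(1))
  se <- sqrt(0.05 * 0.95 / (1500 * 5))
  expect_lt(abs(mean(rates) - 0.05), 4 * se)
})
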