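make_cohort <- function(values, groups = NULL, covariates = NULL, id = "C") {
  if (is.null(groups))
    groups <- stats::setNames(rep("disease", ncol(values)), colnames(values))
  expression_dataset(values, "intensity", groups, dataset_id = id,
                     covariates = covariates, log_scale = TRUE)
}

test_that("the score is the equal-weight mean of measured signature genes", {
  sig <- sprintf("Z%d", 1:9)
  m <- matrix(rep(1:9, 3), nrow = 9,
              dimnames = list(sig, paste0("s", 1:3)))
  ds <- make_cohort(m)
  expect_equal(unname(compute_score(ds, sig)), rep(5, 3))

  const <- m; const[] <- 2.5
  expect_equal(unname(compute_score(make_cohort(const), sig)), rep(2.5, 3))

  # permuting gene order and adding non-signature genes changes nothing
  extra <- rbind(m[sample(9), ], OTHER1 = 99, OTHER2 = -99)
  expect_equal(compute_score(make_cohort(extra), sig), compute_score(ds, sig))

  # too few measured genes errors, listing the missing symbols
  short <- m[1:3, ]
  expect_error(compute_score(make_cohort(short), sig), "Z4")
  expect_silent(compute_score(make_cohort(m[1:5, ]), sig))  # 5 of 9 >= ceiling(4.5)
})

test_that("adding a constant shifts scores exactly and keeps quartiles", {
  set.seed(41)
  sig <- sprintf("Z%d", 1:9)
  m <- matrix(rnorm(9 * 12, 8), 9, 12, dimnames = list(sig, sprintf("s%02d", 1:12)))
  ds <- make_cohort(m)
  s0 <- compute_score(ds, sig)
  shifted <- make_cohort(m + 1.7)
  expect_equal(compute_score(shifted, sig), s0 + 1.7, tolerance = 1e-12)
  expect_identical(quartile_stratify(compute_score(shifted, sig)),
                   quartile_stratify(s0))
})

test_that("score LOG2FC is the group contrast and averages the per-gene values", {
  set.seed(42)
  sig <- sprintf("Z%d", 1:9)
  samples <- sprintf("s%02d", 1:20)
  m <- matrix(rnorm(9 * 20, 8, 0.3), 9, 20, dimnames = list(sig, samples))
  groups <- stats::setNames(rep(c("disease", "healthy"), each = 10), samples)
  m[, 1:10] <- m[, 1:10] - 1  # exact -1 shift
  ds <- make_cohort(m, groups)
  lfc <- score_log2fc(ds, sig)
  mean_gene <- mean(lfc$per_gene$log2fc)
  expect_equal(lfc$score_log2fc, mean_gene, tolerance = 1e-12)  # linearity

  # disease == healthy distributionally (same samples duplicated) -> 0
  mm <- cbind(m[, 11:20], m[, 11:20])
  colnames(mm) <- c(paste0("d", 1:10), paste0("h", 1:10))
  dup <- make_cohort(mm, stats::setNames(rep(c("disease", "healthy"), each = 10),
                                         colnames(mm)))
  expect_equal(score_log2fc(dup, sig)$score_log2fc, 0, tolerance = 1e-12)

  only <- make_cohort(m, stats::setNames(rep("disease", 20), samples))
  expect_error(score_log2fc(only, sig), "two group levels")
})

test_that("score LOG2FC recovers a planted shift within the CLT bound", {
  set.seed(43)
  sig <- sprintf("Z%d", 1:9)
  samples <- sprintf("s%02d", 1:40)
  groups <- stats::setNames(rep(c("disease", "healthy"), each = 20), samples)
  m <- matrix(rnorm(9 * 40, 8, 0.2), 9, 40, dimnames = list(sig, samples))
  m[, 1:20] <- m[, 1:20] - 0.5
  lfc <- score_log2fc(make_cohort(m, groups), sig)
  expect_lt(abs(lfc$score_log2fc - (-0.5)), 0.15)
})

test_that("quartile stratification follows the descending-rank rule", {
  s8 <- stats::setNames(8:1, sprintf("s%d", 1:8))
  q8 <- quartile_stratify(s8)
  expect_identical(as.integer(table(q8)), rep(2L, 4))
  expect_identical(unname(q8[c("s1", "s8")]), c(1L, 4L))

  s10 <- stats::setNames(10:1, sprintf("s%02d", 1:10))
  q10 <- quartile_stratify(s10)
  expect_identical(as.integer(table(q10)), c(3L, 2L, 3L, 2L))

  tied <- stats::setNames(rep(1, 4), c("b", "a", "d", "c"))
  qt <- quartile_stratify(tied)
  expect_identical(qt[order(names(qt))], stats::setNames(1:4, c("a", "b", "c", "d")))

  expect_error(quartile_stratify(c(a = 1, b = 2, c = 3)), "at least 4")
})

test_that("rank-sum test: exact enumeration and approximation agree", {
  same <- rank_sum_test(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$p, 1)

  sep <- rank_sum_test(6:10, 1:5)
  expect_equal(sep$p, 2 / 252, tolerance = 1e-12)
  expect_equal(sep$U, 25)

  # the continuity-corrected normal approximation tracks exact enumeration
  # over every achievable U at 6 vs 6 (worst case sits at the tails)
  sig6 <- sqrt(6 * 6 * 13 / 12)
  combs <- utils::combn(12, 6)
  Us <- colSums(matrix((1:12)[combs], nrow = 6)) - 21
  for (U in 0:36) {
    exact <- mean(abs(Us - 18) >= abs(U - 18) - 1e-12)
    z <- max(0, abs(U - 18) - 0.5) / sig6
    expect_lt(abs(exact - min(1, 2 * pnorm(z, lower.tail = FALSE))), 0.02)
  }
  # the exact branch agrees with wilcox.test's exact p on untied data
  set.seed(44)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.8)
    expect_equal(rank_sum_test(a, b)$p,
                 suppressWarnings(wilcox.test(a, b, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }

  # ties: fully tied data must not yield a spurious signal
  expect_equal(rank_sum_test(rep(1, 3), rep(1, 3))$p, 1)
})

test_that("covariate correlation handles exact, missing and degenerate cases", {
  set.seed(45)
  scores <- stats::setNames(rnorm(30), sprintf("s%02d", 1:30))
  cov <- data.frame(SELF = scores, NEG = -scores, FLAT = rep(2, 30),
                    row.names = names(scores))
  cov$NOISY <- scores * 0.8 + rnorm(30, sd = 0.5)
  cov$NOISY[1:3] <- NA
  expect_warning(res <- correlate_covariates(scores, cov), "zero variance")
  expect_equal(res$r[res$covariate == "SELF"], 1, tolerance = 1e-12)
  expect_equal(res$r[res$covariate == "NEG"], -1, tolerance = 1e-12)
  expect_true(is.na(res$r[res$covariate == "FLAT"]))
  expect_equal(res$n[res$covariate == "NOISY"], 27)  # pairwise deletion
  ct <- cor.test(scores[4:30], cov$NOISY[4:30])
  expect_equal(res$p[res$covariate == "NOISY"], ct$p.value, tolerance = 1e-12)
})

test_that("score_cohort bundles scores, quartiles, contrast and correlations", {
  co <- simulate_disease_cohort(n_disease = 12, n_healthy = 8, n_genes = 200,
                                seed = 46)
  sc <- score_cohort(co$dataset, co$truth$signature)
  expect_s3_class(sc, "scored_cohort")
  expect_length(sc$score, 20)
  expect_true(all(sc$quartile %in% 1:4))
  expect_lt(sc$log2fc$score_log2fc, 0)
  expect_true(all(c("AST", "ALB") %in% sc$correlations$covariate))
  expect_output(summary(sc), "Covariate correlations")
  # predict() on a signature object routes to the same scoring
  sim <- simulate_treatment_datasets(n_datasets = 4, n_intensity = 2, n_counts = 2,
                                     n_genes = 200, seed = 47)
  sig <- suppressWarnings(derive_signature(sim$datasets, min_votes = 3))
  if (length(sig$genes)) {
    pr <- predict(sig, co$dataset, control = NA)
    expect_s3_class(pr, "scored_cohort")
  }
})
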