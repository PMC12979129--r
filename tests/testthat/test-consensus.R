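test_that("vote counting tallies up-calls over measured datasets only", {
  ids <- sprintf("D%02d", 1:11)
  genes <- c("MT1A", "MT1B", "MT1C")
  de <- lapply(seq_along(ids), function(i) {
    up <- character(0)
    if (i <= 5) up <- c(up, "MT1A")          # 5 of 11
    if (i <= 4) up <- c(up, "MT1B")          # 4 of 11
    measured <- if (i <= 3) genes else setdiff(genes, "MT1C")
    make_de(genes, up = up, measured = measured,
            log2fc = c(MT1A = 1, MT1B = 1, MT1C = 2), id = ids[i])
  })
  names(de) <- ids
  ct <- vote_count(de)
  tab <- ct$table
  expect_equal(tab$votes_up[tab$gene == "MT1A"], 5)
  expect_equal(tab$n_measured[tab$gene == "MT1C"], 3)
  prelim <- assemble_preliminary(ct, min_votes = 5)
  expect_identical(prelim, "MT1A")           # 4 votes excluded, 3-measured excluded

  # gene up in all 3 datasets measuring it still fails the absolute threshold
  de3 <- lapply(de, function(d) { d$up[d$gene == "MT1C" & d$measured] <- TRUE; d })
  ct3 <- vote_count(de3)
  expect_equal(ct3$table$votes_up[ct3$table$gene == "MT1C"], 3)
  expect_identical(assemble_preliminary(ct3, min_votes = 5), "MT1A")
  # ...but passes under the relative denominator
  rel <- assemble_preliminary(ct3, min_votes = 5, relative = TRUE)
  expect_true("MT1C" %in% rel)
})

test_that("raising the vote threshold never enlarges the preliminary list", {
  sim <- simulate_treatment_datasets(n_datasets = 6, n_intensity = 3, n_counts = 3,
                                     n_genes = 300, seed = 31)
  de <- lapply(sim$datasets, run_de)
  names(de) <- vapply(sim$datasets, function(d) d$dataset_id, character(1))
  ct <- vote_count(de)
  sizes <- vapply(1:6, function(k) {
    length(suppressWarnings(assemble_preliminary(ct, min_votes = k)))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
  # at the maximum threshold only genes up everywhere remain
  expect_setequal(suppressWarnings(assemble_preliminary(ct, min_votes = 6)),
                  ct$table$gene[ct$table$votes_up == 6])
})

test_that("preliminary ordering breaks vote ties by effect size then symbol", {
  de <- list(
    A = make_de(c("ZB", "ZA", "ZC"), up = c("ZB", "ZA", "ZC"),
                log2fc = c(ZB = 2, ZA = 2, ZC = 3), id = "A"),
    B = make_de(c("ZB", "ZA", "ZC"), up = c("ZB", "ZA", "ZC"),
                log2fc = c(ZB = 2, ZA = 2, ZC = 3), id = "B"))
  out <- assemble_preliminary(vote_count(de), min_votes = 2)
  expect_identical(out, c("ZC", "ZA", "ZB"))  # ZA before ZB on the symbol tie
})

test_that("hypergeometric ORA matches exact enumeration", {
  universe <- sprintf("U%02d", 1:10)
  o <- ora_hypergeom(universe[1:5], universe[1:5], universe)
  expect_equal(o$overlap, 5)
  expect_equal(o$p, 1 / 252, tolerance = 1e-12)

  expect_equal(ora_hypergeom(character(0), universe[1:5], universe)$p, 1)

  set.seed(32)
  for (i in 1:20) {
    U <- sample(6:12, 1)
    uni <- sprintf("U%02d", seq_len(U))
    R <- sample(1:U, 1); q <- sample(1:U, 1)
    ref <- uni[seq_len(R)]
    query <- sample(uni, q)
    o <- ora_hypergeom(query, ref, uni)
    expect_equal(o$p, hyper_upper_brute(o$overlap, R, U, q), tolerance = 1e-12)
  }

  expect_error(ora_hypergeom(c("U01", "NOPE"), universe[1:2], universe), "NOPE")
})

test_that("stress filtering removes member genes and flags confounded datasets", {
  stress <- gene_sets(list(STRESS = c("HSPA6", "DDIT3", "DNAJB1")))
  prelim <- c("MT1A", "HSPA6", "MT1E", "DDIT3")
  out <- filter_stress(prelim, stress)
  expect_identical(out$genes, c("MT1A", "MT1E"))
  expect_setequal(out$flagged, c("HSPA6", "DDIT3"))
  expect_length(intersect(out$genes, unlist(stress)), 0L)

  expect_warning(idf <- filter_stress(prelim, NULL), "no stress sets")
  expect_identical(idf$genes, prelim)

  # a dataset whose up list is dominated by stress genes is reported
  uni <- c(sprintf("G%03d", 1:200), "HSPA6", "DDIT3", "DNAJB1")
  up_stressy <- c("HSPA6", "DDIT3", "DNAJB1", "G001")
  up_clean <- c("G002", "G003", "G004", "G005")
  out2 <- filter_stress(prelim, stress,
                        per_dataset_up = list(S1 = up_stressy, S2 = up_clean),
                        per_dataset_universe = list(S1 = uni, S2 = uni))
  expect_identical(out2$confounded, "S1")
})

test_that("depletion validation assigns the three statuses", {
  de <- make_de(c("MT1A", "MT1F", "SLC30A1"),
                up = "SLC30A1", down = "MT1A",
                measured = c("MT1A", "MT1F", "SLC30A1"), id = "DEP")
  st <- validate_with_depletion(c("MT1A", "MT1F", "SLC30A1", "MT1X"), list(de))
  expect_identical(as.character(st$depletion_status),
                   c("validated", "unmeasured", "discordant", "unmeasured"))
  # discordance in any dataset overrides a down-call elsewhere
  de2 <- make_de("SLC30A1", down = "SLC30A1", id = "DEP2")
  st2 <- validate_with_depletion("SLC30A1", list(de, de2))
  expect_identical(as.character(st2$depletion_status), "discordant")
})

test_that("signature derivation recovers planted genes end-to-end", {
  sim <- simulate_treatment_datasets(n_datasets = 6, n_intensity = 3,
                                     n_counts = 3, n_genes = 400,
                                     high_dose_datasets = 2, seed = 33)
  dep <- simulate_depletion_dataset(n_genes = 400, seed = 34,
                                    discordant_genes = "SLC30A1")
  sig <- derive_signature(sim$datasets, depletion = list(dep$dataset),
                          stress_sets = default_stress_sets(), min_votes = 4)
  expect_gte(length(intersect(sig$genes, sim$truth$zinc_genes)), 8)
  expect_length(intersect(sig$genes, sim$truth$stress_genes), 0L)
  st <- sig$table$depletion_status[match("SLC30A1", sig$table$gene)]
  expect_identical(st, "discordant")
  expect_s3_class(sig, "zinc_signature")
  expect_output(print(sig), "Zinc signature")
})
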