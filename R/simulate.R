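#' @keywords internal
.zinc_pool <- c("MT1A", "MT1E", "MT1F", "MT1G", "MT1M", "SLC30A1",
                "MT1X", "MT2A", "SLC39A10", "MT1B", "MT1H", "MT2P1")

#' @keywords internal
.stress_pool <- c("HSPA6", "DDIT3", "DNAJB1", "HSPA1A", "HSPA1B", "ATF3",
                  "GADD45A", "JUN", "HSPB1", "DNAJA1")

# one intensity matrix on the log2 scale: baseline N(mu_g, sigma_g^2),
# mu_g ~ U(4,12), sigma_g ~ U(0.2,0.6), log2 shifts added to treated columns
.sim_intensity <- function(genes, treated, control, shifts) {
  G <- length(genes)
  mu <- stats::runif(G, 4, 12)
  sig <- stats::runif(G, 0.2, 0.6)
  cols <- c(treated, control)
  m <- mu + sig * matrix(stats::rnorm(G * length(cols)), G, length(cols))
  dimnames(m) <- list(genes, cols)
  m[names(shifts), treated] <- m[names(shifts), treated] + shifts
  m
}

# one negative-binomial count matrix: gene means from a log-normal baseline
# (meanlog 5, sdlog 1.5 - typical bulk RNA-seq spread), dispersion 0.1;
# log2 shifts act multiplicatively (2^shift) on treated means
.sim_counts <- function(genes, treated, control, shifts, dispersion = 0.1) {
  G <- length(genes)
  lam <- stats::rlnorm(G, meanlog = 5, sdlog = 1.5)
  cols <- c(treated, control)
  mu <- matrix(lam, G, length(cols), dimnames = list(genes, cols))
  mu[names(shifts), treated] <- mu[names(shifts), treated] * 2^shifts
  m <- matrix(stats::rnbinom(G * length(cols), mu = mu, size = 1 / dispersion),
              G, length(cols), dimnames = list(genes, cols))
  m
}

.sim_gene_universe <- function(n_genes, n_zinc, n_stress) {
  if (n_zinc > length(.zinc_pool) || n_stress > length(.stress_pool))
    stop("requested more planted genes than the built-in symbol pools hold")
  zinc <- .zinc_pool[seq_len(n_zinc)]
  stress <- .stress_pool[seq_len(n_stress)]
  n_bg <- n_genes - n_zinc - n_stress
  if (n_bg <= 0) stop("n_zinc + n_stress must be smaller than n_genes")
  list(zinc = zinc, stress = stress,
       genes = c(zinc, stress, sprintf("GENE%05d", seq_len(n_bg))))
}

#' Simulate a panel of zinc-treatment datasets
#'
#' Generates heterogeneous two-group treatment datasets with the statistical
#' structure the derivation pipeline assumes: a mix of microarray-like
#' intensity datasets (log2-normal) and RNA-seq count datasets (negative
#' binomial, dispersion 0.1), planted zinc-responsive genes up-shifted in
#' every treated group, stress-response genes up-shifted only in a subset of
#' "high-dose" datasets, and per-dataset gene dropout emulating platform
#' coverage differences (planted zinc genes are never dropped below 8
#' measured datasets).  All generators are pure functions of their
#' parameters and the seed.
#'
#' @param n_datasets total datasets (default 11).
#' @param n_intensity,n_counts platform split (defaults 6 + 5; must sum to
#'   `n_datasets`).
#' @param n_genes genes per dataset before dropout (default 2000).
#' @param n_per_group samples per group (default 4).
#' @param zinc_effect_log2 planted log2 induction of zinc genes (default 1.5).
#' @param n_zinc number of planted zinc genes (default 9).
#' @param n_stress number of planted stress genes (default 6).
#' @param stress_effect_log2 stress induction in high-dose datasets
#'   (default 2.0).
#' @param high_dose_datasets how many datasets carry the stress response
#'   (default 3).
#' @param measured_fraction per-gene per-dataset probability of being
#'   measured (default 0.85).
#' @param seed RNG seed.
#' @return List: `datasets` (list of `zinc_dataset`), `truth`
#'   (planted genes, effects, high-dose ids, measured map, parameters).
#' @export
simulate_treatment_datasets <- function(n_datasets = 11, n_intensity = 6,
                                        n_counts = 5, n_genes = 2000,
                                        n_per_group = 4,
                                        zinc_effect_log2 = 1.5, n_zinc = 9,
                                        n_stress = 6,
                                        stress_effect_log2 = 2.0,
                                        high_dose_datasets = 3,
                                        measured_fraction = 0.85, seed = 1) {
  if (n_intensity + n_counts != n_datasets)
    stop("n_intensity + n_counts must equal n_datasets")
  if (high_dose_datasets > n_datasets)
    stop("high_dose_datasets exceeds n_datasets")
  uni <- .sim_gene_universe(n_genes, n_zinc, n_stress)
  set.seed(seed)
  high_dose <- sort(sample.int(n_datasets, high_dose_datasets))
  platforms <- c(rep("intensity", n_intensity), rep("counts", n_counts))
  ids <- sprintf("SIM%02d", seq_len(n_datasets))
  measured <- matrix(stats::runif(n_genes * n_datasets) < measured_fraction,
                     n_genes, n_datasets, dimnames = list(uni$genes, ids))
  min_meas <- min(8L, n_datasets)
  for (g in uni$zinc) {       # keep planted genes measurable for voting
    short <- min_meas - sum(measured[g, ])
    if (short > 0) {
      off <- which(!measured[g, ])
      measured[g, off[sample.int(length(off), short)]] <- TRUE
    }
  }
  datasets <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    gd <- uni$genes[measured[, d]]
    treated <- sprintf("%s_T%d", ids[d], seq_len(n_per_group))
    control <- sprintf("%s_C%d", ids[d], seq_len(n_per_group))
    shifts <- stats::setNames(rep(zinc_effect_log2, length(intersect(uni$zinc, gd))),
                              intersect(uni$zinc, gd))
    if (d %in% high_dose) {
      sg <- intersect(uni$stress, gd)
      shifts <- c(shifts, stats::setNames(rep(stress_effect_log2, length(sg)), sg))
    }
    m <- if (platforms[d] == "intensity")
      .sim_intensity(gd, treated, control, shifts)
    else
      .sim_counts(gd, treated, control, shifts)
    groups <- stats::setNames(rep(c("treated", "control"), each = n_per_group),
                              c(treated, control))
    datasets[[d]] <- expression_dataset(m, platforms[d], groups,
                                        dataset_id = ids[d],
                                        log_scale = platforms[d] == "intensity")
  }
  truth <- list(zinc_genes = uni$zinc, zinc_effect_log2 = zinc_effect_log2,
                stress_genes = uni$stress,
                stress_effect_log2 = stress_effect_log2,
                high_dose_datasets = ids[high_dose],
                measured = apply(measured, 1L, function(v) ids[v], simplify = FALSE),
                params = list(n_datasets = n_datasets, n_intensity = n_intensity,
                              n_counts = n_counts, n_genes = n_genes,
                              n_per_group = n_per_group,
                              measured_fraction = measured_fraction,
                              seed = seed))
  list(datasets = datasets, truth = truth)
}

#' Simulate a zinc-depletion dataset
#'
#' Intensity-platform two-group dataset in which the planted zinc genes are
#' shifted *down* by `|depletion_effect_log2|` in the depleted samples;
#' genes listed in `discordant_genes` are shifted up instead, emulating
#' paradoxical responders under chelation.
#'
#' @param dataset_id identifier (default "DEP1").
#' @param n_genes genes (default 2000).
#' @param n_per_group samples per group (default 6).
#' @param depletion_effect_log2 log2 shift in depleted samples
#'   (default -1.0; the sign is forced negative).
#' @param discordant_genes subset of the planted zinc genes to shift up
#'   (error when not planted).
#' @param n_zinc number of planted zinc genes (default 9).
#' @param measured_fraction per-gene measurement probability (default 1).
#' @param seed RNG seed.
#' @return List: `dataset` (a `zinc_dataset`), `truth`.
#' @export
simulate_depletion_dataset <- function(dataset_id = "DEP1", n_genes = 2000,
                                       n_per_group = 6,
                                       depletion_effect_log2 = -1.0,
                                       discordant_genes = NULL, n_zinc = 9,
                                       measured_fraction = 1, seed = 1) {
  uni <- .sim_gene_universe(n_genes, n_zinc, 0L)
  bad <- setdiff(discordant_genes, uni$zinc)
  if (length(bad))
    stop("discordant genes not in planted set: ", paste(bad, collapse = ", "))
  eff <- -abs(depletion_effect_log2)
  set.seed(seed)
  keep <- stats::runif(n_genes) < measured_fraction
  keep[match(uni$zinc, uni$genes)] <- TRUE
  gd <- uni$genes[keep]
  depleted <- sprintf("%s_D%d", dataset_id, seq_len(n_per_group))
  control <- sprintf("%s_C%d", dataset_id, seq_len(n_per_group))
  shifts <- stats::setNames(rep(eff, n_zinc), uni$zinc)
  shifts[discordant_genes] <- abs(eff)
  m <- .sim_intensity(gd, depleted, control, shifts[names(shifts) %in% gd])
  groups <- stats::setNames(rep(c("treated", "control"), each = n_per_group),
                            c(depleted, control))
  ds <- expression_dataset(m, "intensity", groups, dataset_id = dataset_id,
                           log_scale = TRUE)
  truth <- list(zinc_genes = uni$zinc, depletion_effect_log2 = eff,
                discordant_genes = discordant_genes %||% character(0),
                params = list(n_genes = n_genes, n_per_group = n_per_group,
                              measured_fraction = measured_fraction,
                              seed = seed))
  list(dataset = ds, truth = truth)
}

#' Simulate a disease cohort with a latent zinc level
#'
#' Every sample receives a latent zinc level `z ~ Normal(0, 1)`, shifted by
#' `disease_shift_log2` in disease samples.  Signature genes load on z with
#' unit weight (`baseline + z + noise`), a planted co-regulated module
#' (acute-phase-like) is generated with population correlation
#' `module_r` to z, and each clinical covariate follows
#' `a + b * z + Normal(0, sigma)`.  This latent construction is the minimal
#' structure that simultaneously yields a score down-shift in disease,
#' covariate correlations of the planted sign, and a score-correlated gene
#' module.
#'
#' @param n_disease,n_healthy group sizes (defaults 41 and 10).
#' @param n_genes genes (default 2000).
#' @param signature character vector of signature genes planted to track z
#'   (default: the 9 built-in zinc symbols).
#' @param disease_shift_log2 latent shift in disease samples (default -1.0).
#' @param module_size,module_r size and target correlation of the planted
#'   module (defaults 20 and 0.7; `module_r` must lie in \[0, 1)).
#' @param covariates named list of `c(a, b, sigma)` per covariate; defaults
#'   to AST falling and albumin rising with z.
#' @param signature_noise_sd per-gene noise around the z loading
#'   (default 0.3 log2 units).
#' @param dataset_id identifier (default "COHORT1").
#' @param seed RNG seed.
#' @return List: `dataset` (a log2-scale `zinc_dataset` with covariates),
#'   `truth` (latent z, planted genes, covariate models, parameters).
#' @export
simulate_disease_cohort <- function(n_disease = 41, n_healthy = 10,
                                    n_genes = 2000,
                                    signature = .zinc_pool[1:9],
                                    disease_shift_log2 = -1.0,
                                    module_size = 20, module_r = 0.7,
                                    covariates = list(AST = c(a = 100, b = -30, sigma = 15),
                                                      ALB = c(a = 30, b = 4, sigma = 2)),
                                    signature_noise_sd = 0.3,
                                    dataset_id = "COHORT1", seed = 1) {
  if (module_r < 0 || module_r >= 1)
    stop("module_r must lie in [0, 1)")
  signature <- unique(toupper(signature))
  module_genes <- sprintf("APR%03d", seq_len(module_size))
  n_bg <- n_genes - length(signature) - module_size
  if (n_bg <= 0) stop("signature + module larger than gene universe")
  bg <- sprintf("GENE%05d", seq_len(n_bg))
  genes <- c(signature, module_genes, bg)
  n <- n_disease + n_healthy
  samples <- sprintf("%s_P%03d", dataset_id, seq_len(n))
  disease <- seq_len(n_disease)
  set.seed(seed)
  z <- stats::rnorm(n)
  z[disease] <- z[disease] + disease_shift_log2
  G <- length(genes)
  base <- stats::runif(G, 4, 12)
  m <- matrix(NA_real_, G, n, dimnames = list(genes, samples))
  i_sig <- seq_along(signature)
  m[i_sig, ] <- base[i_sig] +
    matrix(rep(z, each = length(i_sig)), length(i_sig), n) +
    signature_noise_sd * matrix(stats::rnorm(length(i_sig) * n), length(i_sig), n)
  u <- (z - mean(z)) / stats::sd(z)   # standardized so module_r holds despite the shift
  i_mod <- length(signature) + seq_len(module_size)
  amp <- 0.5
  m[i_mod, ] <- base[i_mod] + amp *
    (module_r * matrix(rep(u, each = module_size), module_size, n) +
     sqrt(1 - module_r^2) * matrix(stats::rnorm(module_size * n), module_size, n))
  i_bg <- (length(signature) + module_size) + seq_len(n_bg)
  sig_bg <- stats::runif(n_bg, 0.2, 0.6)
  m[i_bg, ] <- base[i_bg] + sig_bg * matrix(stats::rnorm(n_bg * n), n_bg, n)
  cov_df <- NULL
  if (length(covariates)) {
    cov_df <- as.data.frame(lapply(covariates, function(cf) {
      cf["a"] + cf["b"] * z + stats::rnorm(n, sd = cf["sigma"])
    }))
    rownames(cov_df) <- samples
  }
  groups <- stats::setNames(c(rep("disease", n_disease), rep("healthy", n_healthy)),
                            samples)
  ds <- expression_dataset(m, "intensity", groups, dataset_id = dataset_id,
                           covariates = cov_df, log_scale = TRUE)
  truth <- list(latent_z = stats::setNames(z, samples),
                signature = signature, module_genes = module_genes,
                module_r = module_r, disease_shift_log2 = disease_shift_log2,
                covariate_model = covariates,
                params = list(n_disease = n_disease, n_healthy = n_healthy,
                              n_genes = n_genes, module_size = module_size,
                              signature_noise_sd = signature_noise_sd,
                              seed = seed))
  list(dataset = ds, truth = truth)
}
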