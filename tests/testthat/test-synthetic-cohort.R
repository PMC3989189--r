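test_that("genotype frequencies match HWE binomial expectations", {
  cfg <- sim_config(n_individuals = 10000L, n_snps = 5L, n_probes = 0L,
                    maf_range = c(0.5, 0.5), ld_decay = 0, seed = 11L)
  g <- simulate_genotypes(cfg)$dosage
  # at MAF 0.5 genotype probabilities are (0.25, 0.5, 0.25)
  n <- nrow(g)
  for (j in seq_len(ncol(g))) {
    freq <- tabulate(g[, j] + 1L, nbins = 3) / n
    expect_lt(abs(freq[1] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
    expect_lt(abs(freq[2] - 0.50), 3 * sqrt(0.50 * 0.50 / n))
    expect_lt(abs(freq[3] - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  }
})

test_that("generators are deterministic and degenerate sizes are allowed", {
  cfg <- default_sim(seed = 5L)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  e1 <- simulate_expression(g1, cfg)
  e2 <- simulate_expression(g2, cfg)
  expect_identical(e1$expression, e2$expression)
  expect_identical(e1$truth$planted_cis, e2$truth$planted_cis)

  empty <- sim_config(n_individuals = 10L, n_snps = 0L, n_probes = 3L, seed = 1L)
  g0 <- simulate_genotypes(empty)
  expect_equal(ncol(g0$dosage), 0)
  expect_equal(nrow(g0$dosage), 10)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(n_snps = 10, cis_effects =
    list(list(snp = 11, probe = 1, beta = 1))), "cis_effects")
  expect_error(sim_config(n_probes = 5, trans_hotspots =
    list(list(snp = 1, probes = 6, betas = 1))), "trans_hotspots")
  expect_error(sim_config(trait_models = list(list(name = "t", beta = 1))),
               "trait_models")
})

test_that("null expression is centered noise and noiseless cis is exact", {
  cfg <- sim_config(n_individuals = 400L, n_snps = 5L, n_probes = 10L,
                    n_confounders = 0L, noise_sd = 1, seed = 21L)
  sim <- simulate_expression(simulate_genotypes(cfg), cfg)
  mu <- colMeans(sim$expression)
  expect_true(all(abs(mu) < 3 * 1 / sqrt(400) + 1e-12))
  expect_equal(nrow(sim$truth$planted_cis), 0)

  cfg0 <- sim_config(n_individuals = 50L, n_snps = 5L, n_probes = 2L,
                     n_confounders = 0L, noise_sd = 0,
                     cis_effects = list(list(snp = 2L, probe = 1L, beta = 1.0)),
                     seed = 22L)
  g <- simulate_genotypes(cfg0)
  sim0 <- simulate_expression(g, cfg0)
  fit <- regress_single(g$dosage[, 2], sim0$expression[, 1])
  expect_equal(fit$beta, 1.0, tolerance = 1e-12)
})

test_that("planted hotspot targets correlate with the source SNP in sign", {
  cfg <- sim_config(n_individuals = 900L, n_snps = 30L, n_probes = 100L,
                    maf_range = c(0.2, 0.4), ld_decay = 0.5,
                    trans_hotspots = list(list(snp = 7L, probes = 1:13,
                                               betas = 0.5)),
                    n_confounders = 0L, noise_sd = 1, seed = 33L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  expect_equal(nrow(sim$truth$planted_trans), 13)
  for (j in 1:13) {
    expect_gt(cor(g$dosage[, 7], sim$expression[, j]), 0)
  }
})

test_that("truth ledger lists every nonzero planted effect exactly once", {
  cfg <- default_sim(seed = 9L)
  sim <- simulate_expression(simulate_genotypes(cfg), cfg)
  planted <- rbind(sim$truth$planted_cis, sim$truth$planted_trans)
  expect_equal(nrow(planted), 2 + 6)
  expect_false(anyDuplicated(planted[, c("snp_id", "probe_id")]) > 0)
  # zero-beta entries are excluded from the ledger
  cfg0 <- sim_config(n_individuals = 20L, n_snps = 5L, n_probes = 5L,
                     cis_effects = list(list(snp = 1L, probe = 1L, beta = 0)),
                     seed = 2L)
  sim0 <- simulate_expression(simulate_genotypes(cfg0), cfg0)
  expect_equal(nrow(sim0$truth$planted_cis), 0)
})

test_that("simulated SNPs pass the HWE exact test at the QC threshold", {
  cfg <- sim_config(n_individuals = 1000L, n_snps = 1000L, n_probes = 0L,
                    maf_range = c(0.1, 0.5), ld_block_size = 10L,
                    ld_decay = 0.8, seed = 17L)
  st <- snp_stats(simulate_genotypes(cfg))
  expect_gte(mean(st$hwe_p > 1e-6), 0.99)
})

test_that("traits follow their configured models", {
  cfg <- sim_config(
    n_individuals = 1000L, n_snps = 5L, n_probes = 5L, n_confounders = 0L,
    trait_models = list(
      list(name = "null_trait", probe = 1L, beta = 0, noise_sd = 1),
      list(name = "exact_trait", probe = 2L, beta = 2, noise_sd = 0),
      list(name = "noisy_trait", probe = 3L, beta = 1, noise_sd = 1),
      list(name = "snp_trait", snp = 1L, beta = 0.5, noise_sd = 1)
    ), seed = 44L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  tr <- simulate_traits(sim$expression, g, cfg)
  expect_identical(colnames(tr),
                   c("null_trait", "exact_trait", "noisy_trait", "snp_trait"))
  n <- nrow(tr)
  expect_lt(abs(cor(tr[, "null_trait"], sim$expression[, 1])), 3 / sqrt(n))
  expect_equal(tr[, "exact_trait"], 2 * sim$expression[, 2],
               tolerance = 1e-12, ignore_attr = TRUE)
  # with unit-variance source and unit noise, r^2 -> var/(var+1) = 1/2
  r2 <- cor(tr[, "noisy_trait"], sim$expression[, 3])^2
  v <- var(sim$expression[, 3])
  expect_equal(r2, v / (v + 1), tolerance = 0.1)
  expect_gt(cor(tr[, "snp_trait"], g$dosage[, 1]), 0)
})

test_that("replication cohorts share the truth but not the realization", {
  cfg <- default_sim(seed = 3L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  repA <- simulate_replication_cohort(sim$truth, cfg, new_seed = 101L)
  repB <- simulate_replication_cohort(sim$truth, cfg, new_seed = 202L)
  expect_identical(repA$truth, sim$truth)
  expect_identical(repB$truth, sim$truth)
  expect_false(identical(repA$genotypes$dosage, repB$genotypes$dosage))
  expect_false(identical(repA$expression, repB$expression))
  # planted signs carry over to the replication realization
  for (k in seq_len(nrow(sim$truth$planted_cis))) {
    pc <- sim$truth$planted_cis[k, ]
    r <- cor(repA$genotypes$dosage[, pc$snp_id], repA$expression[, pc$probe_id])
    expect_equal(sign(r), sign(pc$beta))
  }
})
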