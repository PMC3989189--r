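test_that("replication thresholds and percentage accounting match by hand", {
  th <- replication_thresholds(4116, 161, 0.05)
  expect_equal(signif(th$cis, 3), 1.21e-5)
  expect_equal(signif(th$trans, 2), 3.1e-4)
  expect_equal(replication_thresholds(1, 1, 0.05), list(cis = 0.05, trans = 0.05))
  expect_error(replication_thresholds(0, 10), "positive")
  expect_equal(percent_of(3847, 4210), 91)
  expect_equal(percent_of(3768, 4116), 92)
  expect_equal(percent_of(79, 94), 84)
  # half-away-from-zero at the boundary
  expect_equal(round_half_up(91.5), 92)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("proxy search returns the SNP itself, the best proxy, or nothing", {
  set.seed(40)
  n <- 500
  base <- hwe_dosage(n, 0.3)
  D <- cbind(base, ld_copy(base, 5), ld_copy(base, 60), hwe_dosage(n, 0.3))
  ref <- make_geno(D, ids = c("q", "near", "weak", "far"))
  self <- find_proxy("q", ref, c("q", "near"))
  expect_false(self$is_proxy)
  expect_equal(self$r2, 1)
  # q absent: 'near' is a strong block-mate, 'weak' is below threshold
  px <- find_proxy("q", ref, c("near", "weak", "far"), r2_min = 0.8)
  expect_identical(px$snp_id, "near")
  expect_true(px$is_proxy)
  expect_gt(px$r2, 0.8)
  expect_null(find_proxy("q", ref, c("weak", "far"), r2_min = 0.8))
  # the window bound excludes distant SNPs
  expect_null(find_proxy("q", ref, "near", r2_min = 0.8, flank = 1L))
})

test_that("calls replicate in shared-truth cohorts and directions harmonize", {
  cfg <- sim_config(
    n_individuals = 400L, n_snps = 40L, n_probes = 30L,
    maf_range = c(0.2, 0.4), ld_block_size = 5L, ld_decay = 0.9,
    cis_effects = list(list(snp = 3L, probe = 1L, beta = 0.8),
                       list(snp = 23L, probe = 2L, beta = -0.8)),
    trans_hotspots = list(list(snp = 33L, probes = 10:14, betas = 0.8)),
    n_confounders = 2L, confounder_sd = 2, noise_sd = 1, seed = 50L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  acfg <- analysis_config(n_pc_cis = 4, n_pc_trans = 2,
                          n_pc_cis_replication = 4)
  disc <- run_discovery(g, sim$expression, sim$annotation, acfg)
  expect_gte(disc$summary$n_cis, 2)
  rep1 <- simulate_replication_cohort(sim$truth, cfg, new_seed = 60L)
  rep2 <- simulate_replication_cohort(sim$truth, cfg, new_seed = 61L)
  res <- run_replication(disc,
                         list(coh1 = list(genotypes = rep1$genotypes,
                                          expression = rep1$expression),
                              coh2 = list(genotypes = rep2$genotypes,
                                          expression = rep2$expression)),
                         acfg)
  s <- res$summary
  expect_gt(s$pct_total, 50)
  # planted, strongly-powered cis leads replicate
  planted_leads <- res$records$class == "cis" &
    res$records$snp_id %in% sim$truth$planted_cis$snp_id
  expect_true(any(res$records$replicated[planted_leads]))
  # every passed record in this shared-truth design is direction-consistent
  for (cn in c("coh1", "coh2")) {
    pc <- res$records[[paste0(cn, "_passed")]]
    dc <- res$records[[paste0(cn, "_direction_consistent")]]
    expect_true(all(dc[!is.na(pc) & pc], na.rm = TRUE))
  }
  # percentages are recomputed from raw counts
  expect_equal(s$pct_cis, percent_of(s$n_cis_replicated, s$n_cis))
  expect_equal(s$pct_total, percent_of(s$n_total_replicated, s$n_total))
})

test_that("replication output is invariant to cohort ordering", {
  cfg <- sim_config(n_individuals = 250L, n_snps = 20L, n_probes = 10L,
                    maf_range = c(0.25, 0.35),
                    cis_effects = list(list(snp = 2L, probe = 1L, beta = 0.9)),
                    n_confounders = 0L, seed = 70L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  acfg <- analysis_config(n_pc_cis = 2, n_pc_trans = 2, n_pc_cis_replication = 2)
  disc <- run_discovery(g, sim$expression, sim$annotation, acfg)
  r1 <- simulate_replication_cohort(sim$truth, cfg, 71L)
  r2 <- simulate_replication_cohort(sim$truth, cfg, 72L)
  cohA <- list(a = list(genotypes = r1$genotypes, expression = r1$expression),
               b = list(genotypes = r2$genotypes, expression = r2$expression))
  resAB <- run_replication(disc, cohA, acfg)
  resBA <- run_replication(disc, rev(cohA), acfg)
  expect_equal(resAB$records$a_p, resBA$records$a_p)
  expect_equal(resAB$records$b_passed, resBA$records$b_passed)
  expect_equal(resAB$summary$n_total_replicated, resBA$summary$n_total_replicated)
})

test_that("allele flips between cohorts are harmonized before sign checks", {
  set.seed(41)
  n <- 300
  g <- hwe_dosage(n, 0.3)
  y <- 0.9 * (g - mean(g)) + rnorm(n, sd = 0.5)
  disc_geno <- make_geno(cbind(g, hwe_dosage(n, 0.3)), ids = c("s1", "s2"))
  expr <- matrix(y, n, 1, dimnames = list(rownames(disc_geno$dosage), "pr1"))
  calls <- data.frame(snp_id = "s1", probe_id = "pr1", beta = 0.9, p = 1e-20,
                      class = "cis", lead = TRUE)
  # replication cohort counts the other allele: dosage flipped, ref/alt swapped
  rep_dos <- cbind(2 - g, hwe_dosage(n, 0.3))
  colnames(rep_dos) <- c("s1", "s2")
  rep_map <- data.frame(snp_id = c("s1", "s2"), chrom = "1",
                        pos = c(10000, 20000), ref = "G", alt = "A")
  rep_geno <- genotype_matrix(rep_dos, rep_map)
  rownames(rep_geno$dosage) <- rownames(expr)
  rec <- replicate_calls(
    calls, list(rc = list(genotypes = rep_geno, expression = expr)),
    thresholds = list(cis = 0.05, trans = 0.05), ref_geno = disc_geno,
    config = analysis_config(n_pc_cis_replication = 0, n_pc_trans = 0))
  expect_true(rec$rc_passed[1])
  expect_lt(rec$rc_beta[1], 0)          # raw slope is flipped
  expect_true(rec$rc_direction_consistent[1])  # but harmonization fixes it
})

test_that("empty replication input yields an empty summary without errors", {
  s <- summarize_replication(data.frame(class = character(0),
                                        replicated = logical(0)),
                             cohort_names = character(0))
  expect_equal(s$n_total, 0)
  expect_true(is.na(s$pct_total))
  expect_true(is.na(s$pct_direction_consistent))
})
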