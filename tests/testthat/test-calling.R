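test_that("Bonferroni thresholds reproduce the canonical values", {
  expect_equal(signif(bonferroni_threshold(8308176, 0.05), 3), 6.02e-9)
  expect_equal(signif(bonferroni_threshold(4116, 0.05), 3), 1.21e-5)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 0.01), 1e-4)
  expect_error(bonferroni_threshold(0), "positive")
})

test_that("cis calling keeps significant pairs and flags one lead per probe", {
  snp_map <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "1",
                        pos = c(100, 200, 300))
  assocs <- data.frame(
    snp_id = c("s1", "s2", "s3", "s1"),
    probe_id = c("pA", "pA", "pA", "pB"),
    n = 100, beta = 0.5, se = 0.1,
    t = 5, p = c(1e-12, 1e-10, 0.5, 1e-9),
    degenerate = FALSE, p_floored = FALSE
  )
  calls <- call_cis(assocs, threshold = 1e-8, snp_map)
  expect_equal(sort(unique(calls$probe_id)), c("pA", "pB"))
  expect_equal(nrow(calls), 3)  # s3 fails the threshold
  expect_identical(calls$snp_id[calls$lead & calls$probe_id == "pA"], "s1")
  expect_equal(sum(calls$lead), 2)
  # equal p: the smaller position wins the lead
  tie <- data.frame(snp_id = c("s2", "s1"), probe_id = "pA", n = 100,
                    beta = 1, se = 0.1, t = 10, p = c(1e-10, 1e-10),
                    degenerate = FALSE, p_floored = FALSE)
  tie_calls <- call_cis(tie, 1e-8, snp_map)
  expect_identical(tie_calls$snp_id[tie_calls$lead], "s1")
})

test_that("dosage r^2 has the expected algebra", {
  set.seed(30)
  x <- hwe_dosage(200, 0.3)
  expect_equal(ld_r2(x, x), 1)
  expect_equal(ld_r2(x, 2 - x), 1)  # allele flip invariance
  expect_true(is.na(ld_r2(x, rep(1, 200))))
  y <- hwe_dosage(10000, 0.3)
  x2 <- hwe_dosage(10000, 0.3)
  expect_lt(ld_r2(x2, y), 0.01)
  # missing entries drop pairwise
  xm <- x; xm[1:50] <- NA
  expect_equal(ld_r2(xm, x), 1)
})

test_that("trans pruning drops cis-linked SNPs and clumps the rest", {
  set.seed(31)
  n <- 400
  base1 <- hwe_dosage(n, 0.3)
  block <- cbind(base1, ld_copy(base1, 3), ld_copy(base1, 5))  # tight LD trio
  ind1 <- hwe_dosage(n, 0.3)
  ind2 <- hwe_dosage(n, 0.4)
  cis_linked <- ld_copy(ind2, 2)   # r^2 > 0.5 with ind2
  D <- cbind(block, ind1, ind2, cis_linked)
  geno <- make_geno(D, ids = c("b1", "b2", "b3", "i1", "i2", "cl"))
  cis_calls <- data.frame(snp_id = "i2")
  trans <- data.frame(
    snp_id = c("b1", "b2", "b3", "i1", "cl"),
    probe_id = "pT", n = n, beta = 0.5, se = 0.05, t = 10,
    p = c(1e-20, 1e-15, 1e-13, 1e-18, 1e-16),
    degenerate = FALSE, p_floored = FALSE
  )
  out <- prune_trans(trans, cis_calls, geno, r2 = 0.5)
  # step 1: cl is in high LD with the cis SNP i2 and is dropped
  expect_equal(out$n_dropped_cis_ld, 1)
  expect_false("cl" %in% out$calls$snp_id)
  # step 2: the LD trio forms one locus led by its smallest-p member
  expect_equal(nrow(out$loci), 2)
  trio_locus <- out$calls$locus_id[out$calls$snp_id == "b1"]
  expect_setequal(out$calls$snp_id[out$calls$locus_id == trio_locus],
                  c("b1", "b2", "b3"))
  expect_identical(out$loci$lead_snp[out$loci$locus_id == trio_locus], "b1")
  # invariants: members tied to lead, leads mutually unlinked
  for (L in seq_len(nrow(out$loci))) {
    lead <- out$loci$lead_snp[L]
    members <- out$calls$snp_id[out$calls$locus_id == out$loci$locus_id[L]]
    for (m in setdiff(members, lead)) {
      expect_gt(ld_r2(geno$dosage[, m], geno$dosage[, lead]), 0.5)
    }
  }
  leads <- out$loci$lead_snp
  if (length(leads) > 1) {
    for (i in 1:(length(leads) - 1)) for (j in (i + 1):length(leads)) {
      expect_lte(ld_r2(geno$dosage[, leads[i]], geno$dosage[, leads[j]]), 0.5)
    }
  }
  # three mutually independent SNPs -> three loci
  D3 <- cbind(hwe_dosage(n, 0.2), hwe_dosage(n, 0.3), hwe_dosage(n, 0.4))
  g3 <- make_geno(D3, ids = c("x1", "x2", "x3"))
  t3 <- data.frame(snp_id = c("x1", "x2", "x3"), probe_id = "pT", n = n,
                   beta = 1, se = 0.1, t = 10, p = c(1e-15, 1e-14, 1e-13),
                   degenerate = FALSE, p_floored = FALSE)
  out3 <- prune_trans(t3, data.frame(snp_id = character(0)), g3)
  expect_equal(nrow(out3$loci), 3)
})

test_that("pruning and calling are invariant to input row order", {
  set.seed(32)
  n <- 300
  base <- hwe_dosage(n, 0.3)
  D <- cbind(base, ld_copy(base, 2), hwe_dosage(n, 0.25), hwe_dosage(n, 0.4))
  geno <- make_geno(D, ids = c("a1", "a2", "c1", "c2"))
  trans <- data.frame(snp_id = c("a1", "a2", "c1", "c2"), probe_id = "pT",
                      n = n, beta = 0.4, se = 0.05, t = 8,
                      p = c(1e-12, 1e-11, 1e-10, 1e-9),
                      degenerate = FALSE, p_floored = FALSE)
  o1 <- prune_trans(trans, data.frame(snp_id = character(0)), geno)
  o2 <- prune_trans(trans[sample(nrow(trans)), ],
                    data.frame(snp_id = character(0)), geno)
  norm <- function(o) o$calls[order(o$calls$snp_id),
                              c("snp_id", "locus_id", "lead")]
  expect_equal(norm(o1), norm(o2), ignore_attr = TRUE)
})

test_that("discovery summary counts add up", {
  cis <- data.frame(snp_id = c("s1", "s2", "s3"),
                    probe_id = c("pA", "pB", "pC"),
                    gene = c("G1", "G1", ""), p = c(1e-10, 1e-9, 1e-9),
                    lead = TRUE)
  pruned <- list(calls = data.frame(snp_id = c("t1", "t2"), probe_id = "pX",
                                    locus_id = c("locus001", "locus001")),
                 loci = data.frame(locus_id = "locus001", lead_snp = "t1"))
  s <- summarize_discovery(cis, pruned)
  expect_equal(s$n_cis, 3)
  expect_equal(s$n_trans_pairs, 2)
  expect_equal(s$n_trans_loci, 1)
  expect_equal(s$total, 4)
  expect_equal(s$n_genes, 1)
  expect_equal(s$n_multiprobe, 1)  # G1 supported by two probes
  expect_equal(s$n_unassigned, 1)
  empty <- summarize_discovery(cis[0, ], list(calls = cis[0, ],
                                              loci = data.frame()))
  expect_equal(empty$total, 0)
})
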