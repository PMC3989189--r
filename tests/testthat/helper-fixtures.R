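# Shared fixture builders for the test suite. All randomness is seeded by
# the caller; nothing here draws from an unset RNG state.

# A genotype matrix built directly from a dosage matrix, with evenly
# spaced positions on one chromosome.
make_geno <- function(dosage, chrom = "1", spacing = 10000L,
                      ids = sprintf("rs%03d", seq_len(ncol(dosage)))) {
  colnames(dosage) <- ids
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  map <- data.frame(snp_id = ids, chrom = chrom,
                    pos = spacing * seq_len(ncol(dosage)),
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

# HWE dosages at a given allele frequency.
hwe_dosage <- function(n, maf) {
  stats::rbinom(n, 1, maf) + stats::rbinom(n, 1, maf)
}

# A high-LD copy of a dosage vector: flip a few entries.
ld_copy <- function(x, n_flips = 2L) {
  y <- x
  i <- seq_len(n_flips)
  y[i] <- 2 - y[i]
  y
}

# Brute-force HWE exact test: enumerate all heterozygote counts compatible
# with the allele counts, weight by the exact conditional distribution.
# Independent of the package implementation (direct factorials, no
# log-space tricks), usable for totals up to ~80.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  na <- 2 * n_hom_alt + n_het   # alt allele count
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  w <- sapply(hets, function(h) {
    aa <- (na - h) / 2
    rr <- n - h - aa
    factorial(n) / (factorial(rr) * factorial(h) * factorial(aa)) * 2^h
  })
  prob <- w / sum(w)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# Small standard simulation: a few cis effects, one hotspot, confounders.
default_sim <- function(seed = 1L, n = 300L) {
  sim_config(
    n_individuals = n, n_snps = 60L, n_probes = 40L,
    maf_range = c(0.2, 0.4), ld_block_size = 6L, ld_decay = 0.9,
    cis_effects = list(list(snp = 5L, probe = 1L, beta = 0.8),
                       list(snp = 25L, probe = 2L, beta = -0.7)),
    trans_hotspots = list(list(snp = 45L, probes = 10:15, betas = 0.7)),
    n_confounders = 3L, confounder_sd = 2, noise_sd = 1, seed = seed
  )
}
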