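#' Hardy-Weinberg exact test
#'
#' Exact conditional test for deviation from Hardy-Weinberg genotype
#' proportions. Conditional on the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose probability does
#' not exceed that of the observed configuration (the standard "no more
#' probable" two-sided definition). Computed in log space with a
#' log-sum-exp normalization, so it is stable up to large sample sizes.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (>= 0, total > 0).
#' @return p-value in (0, 1]; monomorphic SNPs give exactly 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_rare == 0) return(1)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # unnormalized log-probability of each het count given the allele counts
  lp <- hets * log(2) - lfactorial(hets) -
    lfactorial((n_rare - hets) / 2) -
    lfactorial((2 * n - n_rare - hets) / 2)
  lp <- lp - max(lp)
  prob <- exp(lp) / sum(exp(lp))
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

#' SNP-level quality control
#'
#' Applies the standard whole-blood eQTL inclusion filters to a genotype
#' matrix: minor allele frequency, call rate and Hardy-Weinberg exact-test
#' p-value must each strictly exceed the configured thresholds (defaults
#' MAF > 0.05, call rate > 0.95, HWE P > 1e-6). MAF is computed on
#' non-missing calls only. A SNP may fail several filters; each failure is
#' counted once per filter.
#'
#' @param geno a [genotype_matrix].
#' @param config an [analysis_config].
#' @return list with `genotypes` (the filtered [genotype_matrix]) and
#'   `report` (class `qc_report`: totals plus a per-SNP flag table).
#' @export
snp_qc <- function(geno, config = analysis_config()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (ncol(geno$dosage) == 0) stop("genotype matrix has no SNPs")
  st <- snp_stats(geno)
  fail_maf <- !(st$maf > config$maf_min)
  fail_callrate <- !(st$call_rate > config$callrate_min)
  fail_hwe <- !(st$hwe_p > config$hwe_p_min)
  fail_maf[is.na(fail_maf)] <- TRUE
  fail_hwe[is.na(fail_hwe)] <- TRUE
  pass <- !(fail_maf | fail_callrate | fail_hwe)
  report <- structure(list(
    n_input = nrow(st),
    n_pass = sum(pass),
    n_fail_maf = sum(fail_maf),
    n_fail_callrate = sum(fail_callrate),
    n_fail_hwe = sum(fail_hwe),
    per_snp = data.frame(
      snp_id = st$snp_id, maf = st$maf, call_rate = st$call_rate,
      hwe_p = st$hwe_p, fail_maf = fail_maf, fail_callrate = fail_callrate,
      fail_hwe = fail_hwe, pass = pass, stringsAsFactors = FALSE
    )
  ), class = "qc_report")
  list(genotypes = subset_snps(geno, which(pass)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "SNP QC: %d in, %d pass (fail MAF %d, call rate %d, HWE %d)\n",
    x$n_input, x$n_pass, x$n_fail_maf, x$n_fail_callrate, x$n_fail_hwe))
  invisible(x)
}

#' Write a QC report to TSV
#'
#' @param report a `qc_report` from [snp_qc].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(report$per_snp, path, sep = "\t")
  invisible(path)
}
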