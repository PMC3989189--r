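#' Analysis configuration
#'
#' Thresholds and tuning constants of the eQTL pipeline, bundled so that
#' every stage reads from one validated object. Defaults follow the
#' conventions of large whole-blood eQTL studies: a 500 kb cis window
#' around the transcription unit, SNP inclusion filters MAF > 5 percent,
#' call rate > 95 percent and Hardy-Weinberg exact-test P > 1e-6, 55/25
#' expression principal components removed for the cis/trans discovery
#' scans (50 for cis replication), LD pruning at r^2 > 0.5 and a
#' five-gene minimum for master-regulator loci.
#'
#' @param cis_flank cis window half-width in bp around the transcription
#'   unit (start and end inclusive).
#' @param alpha family-wise significance level before Bonferroni division.
#' @param n_pc_cis,n_pc_trans number of expression PCs removed before the
#'   cis and trans discovery scans.
#' @param n_pc_cis_replication number of PCs removed for cis replication.
#' @param maf_min,callrate_min,hwe_p_min SNP inclusion filters; all strict
#'   (a SNP is kept only if its value exceeds the threshold).
#' @param ld_prune_r2 r^2 above which two SNPs are treated as the same
#'   signal during trans pruning and locus clumping.
#' @param proxy_r2_min minimum r^2 for a proxy SNP to stand in for a
#'   discovery SNP absent from a replication cohort.
#' @param master_min_targets minimum number of distinct target genes for a
#'   trans locus to be called a master regulator.
#' @param multi_target_min minimum target count for the multi-target report.
#' @param pc_alpha nominal significance level used to flag PCs associated
#'   with the SNP of interest at replication time.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(cis_flank = 500000L,
                            alpha = 0.05,
                            n_pc_cis = 55L,
                            n_pc_trans = 25L,
                            n_pc_cis_replication = 50L,
                            maf_min = 0.05,
                            callrate_min = 0.95,
                            hwe_p_min = 1e-6,
                            ld_prune_r2 = 0.5,
                            proxy_r2_min = 0.8,
                            master_min_targets = 5L,
                            multi_target_min = 2L,
                            pc_alpha = 0.05) {
  if (cis_flank <= 0) stop_config("cis_flank", "must be positive")
  if (alpha <= 0 || alpha >= 1) stop_config("alpha", "must lie in (0,1)")
  for (nm in c("maf_min", "callrate_min", "hwe_p_min", "ld_prune_r2",
               "proxy_r2_min", "pc_alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0 || v > 1) stop_config(nm, "must lie in [0,1]")
  }
  if (maf_min > 0.5) stop_config("maf_min", "must not exceed 0.5")
  if (master_min_targets < 1) stop_config("master_min_targets", "must be >= 1")
  structure(list(
    cis_flank = as.integer(cis_flank), alpha = alpha,
    n_pc_cis = as.integer(n_pc_cis), n_pc_trans = as.integer(n_pc_trans),
    n_pc_cis_replication = as.integer(n_pc_cis_replication),
    maf_min = maf_min, callrate_min = callrate_min, hwe_p_min = hwe_p_min,
    ld_prune_r2 = ld_prune_r2, proxy_r2_min = proxy_r2_min,
    master_min_targets = as.integer(master_min_targets),
    multi_target_min = as.integer(multi_target_min),
    pc_alpha = pc_alpha
  ), class = "analysis_config")
}

#' Read or write an analysis configuration as YAML
#'
#' @param path file path.
#' @return `read_analysis_config` returns an `analysis_config`;
#'   `write_analysis_config` returns `path` invisibly.
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(analysis_config, vals)
}

#' @rdname read_analysis_config
#' @param config an `analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("eQTL analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
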