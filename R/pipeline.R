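#' Run the discovery stage end to end
#'
#' Chains the discovery pipeline on one cohort: SNP quality control,
#' expression PC residualization (class-specific component counts), the
#' cis-window association scan and the genome-wide trans scan, Bonferroni
#' thresholding, cis lead-SNP selection and trans LD pruning into loci.
#'
#' The cis Bonferroni denominator is the number of enumerated cis pairs;
#' the trans denominator is the total number of SNP-probe combinations
#' (cis pairs are not subtracted), and trans calls are the significant
#' pairs outside the cis enumeration.
#'
#' @param geno discovery [genotype_matrix].
#' @param expr samples x probes expression matrix.
#' @param annotation probe annotation (probe_id, gene, chrom, tx_start,
#'   tx_end).
#' @param config an [analysis_config].
#' @param qc apply [snp_qc] first (disable for pre-filtered input).
#' @return list with `genotypes` (post-QC), `qc_report`, `cis`
#'   (n_tests, threshold, pairs, calls), `trans` (n_tests, threshold,
#'   calls, loci, n_dropped_cis_ld) and `summary` from
#'   [summarize_discovery].
#' @export
run_discovery <- function(geno, expr, annotation, config = analysis_config(),
                          qc = TRUE) {
  expr <- as.matrix(expr)
  qc_report <- NULL
  if (qc) {
    q <- snp_qc(geno, config)
    geno <- q$genotypes
    qc_report <- q$report
  }
  enum <- enumerate_cis_pairs(geno$map, annotation, config$cis_flank)
  n_cis_tests <- enum$n_pairs
  n_trans_tests <- as.numeric(ncol(geno$dosage)) * ncol(expr)
  k_cap <- max(min(nrow(expr) - 1L, ncol(expr)), 0L)
  resid_cis <- residualize(expr, compute_pcs(expr, min(config$n_pc_cis, k_cap)))
  resid_trans <- residualize(expr, compute_pcs(expr, min(config$n_pc_trans, k_cap)))

  cis_threshold <- if (n_cis_tests > 0)
    bonferroni_threshold(n_cis_tests, config$alpha) else NA_real_
  cis_assoc <- if (n_cis_tests > 0)
    assoc_scan(geno, resid_cis, pairs = enum$pairs) else empty_scan_result()
  cis_calls <- call_cis(cis_assoc, cis_threshold, geno$map, annotation)

  trans_threshold <- bonferroni_threshold(max(n_trans_tests, 1), config$alpha)
  all_assoc <- assoc_scan(geno, resid_trans, mode = "all")
  key <- paste(all_assoc$snp_id, all_assoc$probe_id)
  cis_key <- paste(enum$pairs$snp_id, enum$pairs$probe_id)
  trans_sig <- all_assoc[!(key %in% cis_key) & !all_assoc$degenerate &
                           all_assoc$p <= trans_threshold, , drop = FALSE]
  pruned <- prune_trans(trans_sig, cis_calls, geno, r2 = config$ld_prune_r2,
                        annotation = annotation)
  list(
    genotypes = geno, qc_report = qc_report,
    cis = list(n_tests = n_cis_tests, threshold = cis_threshold,
               pairs = enum$pairs, calls = cis_calls),
    trans = list(n_tests = n_trans_tests, threshold = trans_threshold,
                 calls = pruned$calls, loci = pruned$loci,
                 n_dropped_cis_ld = pruned$n_dropped_cis_ld),
    summary = summarize_discovery(cis_calls, pruned)
  )
}

#' Run the replication stage on discovery output
#'
#' Builds the per-class replication thresholds from the discovered
#' association counts (cis SNP-probe calls and trans SNP-probe
#' associations) and replicates every discovery call in each cohort via
#' [replicate_calls].
#'
#' @param discovery output of [run_discovery].
#' @param cohorts named list of cohorts, each `list(genotypes, expression)`
#'   (genotypes QC'd or raw; QC is applied here when `qc = TRUE`).
#' @param config an [analysis_config].
#' @param qc apply SNP QC to each cohort first.
#' @return list with `thresholds`, `records` and `summary`.
#' @export
run_replication <- function(discovery, cohorts, config = analysis_config(),
                            qc = TRUE) {
  cis_calls <- discovery$cis$calls
  trans_calls <- discovery$trans$calls
  n_cis <- sum(isTRUE_vec(cis_calls$lead))
  n_trans <- nrow(trans_calls)
  if (n_cis + n_trans == 0) {
    return(list(thresholds = NULL,
                records = data.frame(),
                summary = summarize_replication(
                  data.frame(class = character(0), replicated = logical(0)),
                  cohort_names = names(cohorts))))
  }
  thresholds <- replication_thresholds(max(n_cis, 1), max(n_trans, 1),
                                       config$alpha)
  if (qc) {
    cohorts <- lapply(cohorts, function(co) {
      co$genotypes <- snp_qc(co$genotypes, config)$genotypes
      co
    })
  }
  calls <- rbind_fill(cis_calls, trans_calls)
  records <- replicate_calls(calls, cohorts, thresholds,
                             ref_geno = discovery$genotypes, config = config)
  list(thresholds = thresholds, records = records,
       summary = summarize_replication(records, names(cohorts)))
}

# rbind two data.frames, filling absent columns with NA.
rbind_fill <- function(a, b) {
  if (nrow(a) == 0) return(b)
  if (nrow(b) == 0) return(a)
  cols <- union(names(a), names(b))
  for (col in setdiff(cols, names(a))) a[[col]] <- NA
  for (col in setdiff(cols, names(b))) b[[col]] <- NA
  rbind(a[, cols, drop = FALSE], b[, cols, drop = FALSE])
}
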