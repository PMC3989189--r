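#' Replication significance thresholds
#'
#' Bonferroni thresholds for the replication stage, dividing alpha by the
#' number of discovered SNP-probe associations per class (e.g. 4,116 cis
#' and 161 trans associations give 1.21e-5 and 3.1e-4 at alpha 0.05).
#' Note the denominators are discovered associations, not pruned loci.
#'
#' @param n_cis_discovered,n_trans_discovered discovered association
#'   counts per class (>= 1).
#' @param alpha family-wise level.
#' @return list with `cis` and `trans` thresholds (full precision).
#' @export
replication_thresholds <- function(n_cis_discovered, n_trans_discovered,
                                   alpha = 0.05) {
  list(cis = bonferroni_threshold(n_cis_discovered, alpha),
       trans = bonferroni_threshold(n_trans_discovered, alpha))
}

#' Find a replication SNP or LD proxy
#'
#' Returns the discovery SNP itself when present in the replication
#' cohort; otherwise the cohort SNP within `flank` bp with the highest
#' r^2 to the discovery SNP (computed in the LD reference panel, normally
#' the discovery cohort), provided r^2 >= `r2_min`. Absence of any
#' adequate proxy is a value, not an error.
#'
#' @param snp_id discovery SNP id.
#' @param ref_geno LD reference [genotype_matrix] containing the SNP.
#' @param cohort_snp_ids SNP ids available in the replication cohort.
#' @param r2_min minimum acceptable proxy r^2 (default 0.8).
#' @param flank search window in bp (default 500 kb).
#' @return list with `snp_id`, `r2` and `is_proxy`, or NULL when no SNP
#'   or proxy qualifies.
#' @export
find_proxy <- function(snp_id, ref_geno, cohort_snp_ids, r2_min = 0.8,
                       flank = 500000L) {
  if (snp_id %in% cohort_snp_ids) {
    return(list(snp_id = snp_id, r2 = 1, is_proxy = FALSE))
  }
  map <- ref_geno$map
  i <- match(snp_id, map$snp_id)
  if (is.na(i)) stop("SNP ", snp_id, " absent from the LD reference")
  cand <- map$snp_id[map$chrom == map$chrom[i] &
                       abs(map$pos - map$pos[i]) <= flank &
                       map$snp_id %in% cohort_snp_ids &
                       map$snp_id != snp_id]
  if (length(cand) == 0) return(NULL)
  r2s <- ld_r2_vec(ref_geno$dosage[, snp_id],
                   ref_geno$dosage[, cand, drop = FALSE])
  j <- which.max(r2s)
  if (is.na(r2s[j]) || r2s[j] < r2_min) return(NULL)
  list(snp_id = cand[j], r2 = r2s[j], is_proxy = TRUE)
}

# Flip factor to harmonize the cohort's effect allele with discovery's:
# +1 same orientation, -1 swapped ref/alt, NA not harmonizable.
allele_flip <- function(disc_ref, disc_alt, rep_ref, rep_alt) {
  if (identical(disc_ref, rep_ref) && identical(disc_alt, rep_alt)) return(1)
  if (identical(disc_ref, rep_alt) && identical(disc_alt, rep_ref)) return(-1)
  NA_real_
}

#' Replicate discovery calls in independent cohorts
#'
#' For every discovery call and every replication cohort, finds the same
#' SNP or an LD proxy, removes the cohort's expression principal
#' components (class-specific counts, minus components associated with
#' the SNP of interest), re-runs the additive regression and applies the
#' replication threshold for the call's class. Effect alleles are
#' harmonized before comparing signs; a call is replicated when it passes
#' in at least one cohort.
#'
#' @param calls discovery calls: rows with snp_id, probe_id, beta, p,
#'   class ("cis"/"trans") and (for trans) locus_id.
#' @param cohorts named list; each element a list with `genotypes` (a
#'   [genotype_matrix], already QC'd) and `expression` (samples x probes).
#' @param thresholds list with `cis` and `trans` replication thresholds,
#'   as from [replication_thresholds].
#' @param ref_geno LD reference for proxy search (discovery genotypes).
#' @param config an [analysis_config]; supplies PC counts
#'   (`n_pc_cis_replication`, `n_pc_trans`), `proxy_r2_min` and `pc_alpha`.
#' @return data.frame of replication records: one row per call with
#'   per-cohort snp_used, proxy_r2, n, beta, p, passed and
#'   direction_consistent columns, plus overall `replicated`.
#' @export
replicate_calls <- function(calls, cohorts, thresholds, ref_geno,
                            config = analysis_config()) {
  stopifnot(length(names(cohorts)) == length(cohorts))
  out <- calls[, intersect(c("snp_id", "probe_id", "beta", "p", "class",
                             "locus_id", "lead", "gene"), names(calls)),
               drop = FALSE]
  names(out)[names(out) == "beta"] <- "beta_discovery"
  names(out)[names(out) == "p"] <- "p_discovery"
  any_passed <- rep(FALSE, nrow(calls))
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    geno <- co$genotypes
    expr <- as.matrix(co$expression)
    k_cis <- min(config$n_pc_cis_replication, min(dim(expr)) - 1L)
    k_trans <- min(config$n_pc_trans, min(dim(expr)) - 1L)
    bases <- list(cis = compute_pcs(expr, max(k_cis, 0)),
                  trans = compute_pcs(expr, max(k_trans, 0)))
    snp_used <- rep(NA_character_, nrow(calls))
    proxy_r2 <- rep(NA_real_, nrow(calls))
    nn <- rep(NA_integer_, nrow(calls))
    bb <- rep(NA_real_, nrow(calls)); pp <- rep(NA_real_, nrow(calls))
    passed <- rep(NA, nrow(calls)); dircon <- rep(NA, nrow(calls))
    # residual cache: probe x (class, excluded-PC set) would be overkill at
    # this scale; residualize per call on single columns instead
    for (i in seq_len(nrow(calls))) {
      cls <- calls$class[i]
      if (!(calls$probe_id[i] %in% colnames(expr))) next
      px <- find_proxy(calls$snp_id[i], ref_geno, geno$map$snp_id,
                       r2_min = config$proxy_r2_min, flank = config$cis_flank)
      if (is.null(px)) { passed[i] <- FALSE; next }
      g <- geno$dosage[, px$snp_id]
      basis <- bases[[cls]]
      excl <- snp_associated_pcs(basis, g, alpha = config$pc_alpha)
      b <- drop_pcs(basis, excl)
      y <- residualize(expr[, calls$probe_id[i], drop = FALSE], b)[, 1]
      r <- regress_single(g, y)
      if (r$degenerate) { passed[i] <- FALSE; next }
      snp_used[i] <- px$snp_id
      proxy_r2[i] <- px$r2
      nn[i] <- r$n; bb[i] <- r$beta; pp[i] <- r$p
      passed[i] <- r$p <= thresholds[[cls]]
      if (passed[i]) {
        di <- match(calls$snp_id[i], ref_geno$map$snp_id)
        ri <- match(px$snp_id, geno$map$snp_id)
        flip <- if (px$is_proxy) {
          # proxies are oriented by their LD reference correlation sign
          s <- sign(stats::cor(ref_geno$dosage[, calls$snp_id[i]],
                               ref_geno$dosage[, px$snp_id],
                               use = "pairwise.complete.obs"))
          if (is.na(s) || s == 0) NA_real_ else s
        } else {
          allele_flip(ref_geno$map$ref[di], ref_geno$map$alt[di],
                      geno$map$ref[ri], geno$map$alt[ri])
        }
        dircon[i] <- !is.na(flip) &&
          sign(calls$beta[i]) == sign(r$beta * flip)
      }
    }
    any_passed <- any_passed | isTRUE_vec(passed)
    block <- data.frame(snp_used, proxy_r2, nn, bb, pp, passed, dircon)
    names(block) <- paste0(cn, "_", c("snp_used", "proxy_r2", "n", "beta",
                                      "p", "passed", "direction_consistent"))
    out <- cbind(out, block)
  }
  out$replicated <- any_passed
  rownames(out) <- NULL
  out
}

#' Summarize replication results
#'
#' Counts and integer percentages of replicated eQTLs, overall and per
#' class, with cis counted as SNP-probe calls and trans as genomic loci
#' (a locus replicates when any of its member associations does).
#' Percentages are rounded half away from zero and are always recomputed
#' from the raw counts. Allelic direction consistency is reported over
#' all (record, cohort) pairs that passed.
#'
#' @param records output of [replicate_calls].
#' @param cohort_names names of the replication cohorts.
#' @return list of counts and percentages; zero-discovery classes give
#'   NA percentages rather than errors.
#' @export
summarize_replication <- function(records,
                                  cohort_names = guess_cohorts(records)) {
  is_cis <- records$class == "cis"
  cis_lead <- is_cis & (if ("lead" %in% names(records))
    isTRUE_vec(records$lead) else TRUE)
  n_cis <- sum(cis_lead)
  n_cis_rep <- sum(cis_lead & records$replicated)
  trans <- records[!is_cis, , drop = FALSE]
  n_trans_pairs <- nrow(trans)
  n_trans_pairs_rep <- sum(trans$replicated)
  if (n_trans_pairs > 0 && "locus_id" %in% names(trans)) {
    loci <- unique(trans$locus_id)
    rep_loci <- unique(trans$locus_id[trans$replicated])
    n_trans_loci <- length(loci)
    n_trans_loci_rep <- length(rep_loci)
  } else {
    n_trans_loci <- 0L; n_trans_loci_rep <- 0L
  }
  n_total <- n_cis + n_trans_loci
  n_total_rep <- n_cis_rep + n_trans_loci_rep
  pct <- function(k, n) if (n > 0) percent_of(k, n) else NA_real_
  # direction consistency over all passed (record, cohort) pairs
  n_pass_pairs <- 0L; n_dir <- 0L
  per_cohort <- list()
  for (cn in cohort_names) {
    pcol <- records[[paste0(cn, "_passed")]]
    dcol <- records[[paste0(cn, "_direction_consistent")]]
    n_pass_pairs <- n_pass_pairs + sum(isTRUE_vec(pcol))
    n_dir <- n_dir + sum(isTRUE_vec(pcol) & isTRUE_vec(dcol))
    per_cohort[[cn]] <- list(
      n_replicated = sum(isTRUE_vec(pcol) &
                           (cis_lead | !is_cis)),
      pct_replicated = pct(sum(isTRUE_vec(pcol) & cis_lead) +
                             count_loci(records, pcol, is_cis),
                           n_total))
  }
  list(
    n_cis = n_cis, n_cis_replicated = n_cis_rep,
    pct_cis = pct(n_cis_rep, n_cis),
    n_trans_pairs = n_trans_pairs,
    n_trans_pairs_replicated = n_trans_pairs_rep,
    n_trans_loci = n_trans_loci,
    n_trans_loci_replicated = n_trans_loci_rep,
    pct_trans = pct(n_trans_loci_rep, n_trans_loci),
    n_total = n_total, n_total_replicated = n_total_rep,
    pct_total = pct(n_total_rep, n_total),
    n_direction_assessed = n_pass_pairs,
    n_direction_consistent = n_dir,
    pct_direction_consistent = if (n_pass_pairs > 0)
      percent_of(n_dir, n_pass_pairs) else NA_real_,
    per_cohort = per_cohort
  )
}

count_loci <- function(records, pcol, is_cis) {
  if (!"locus_id" %in% names(records)) return(0L)
  length(unique(records$locus_id[!is_cis & isTRUE_vec(pcol)]))
}

guess_cohorts <- function(records) {
  nm <- names(records)
  sub("_passed$", "", nm[grepl("_passed$", nm)])
}
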