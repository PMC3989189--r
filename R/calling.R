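#' Bonferroni significance threshold
#'
#' Family-wise threshold `alpha / n_tests`, kept at full precision;
#' rounding to 3 significant figures is a display concern only. With the
#' 8,308,176 possible cis SNP-probe combinations of a genome-wide
#' whole-blood scan and alpha 0.05 this gives 6.02e-9.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise level.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("n_tests must be a positive count")
  }
  alpha / n_tests
}

#' Squared-correlation linkage disequilibrium
#'
#' Composite LD between two SNPs: the squared Pearson correlation of their
#' dosage vectors on pairwise-complete cases. Invariant to allele
#' flipping (dosage -> 2 - dosage).
#'
#' @param dosage1,dosage2 dosage vectors of equal length.
#' @return r^2 in [0,1]; NA when fewer than 3 complete pairs or either
#'   vector is constant.
#' @export
ld_r2 <- function(dosage1, dosage2) {
  ok <- !is.na(dosage1) & !is.na(dosage2)
  if (sum(ok) < 3) return(NA_real_)
  x <- dosage1[ok]; y <- dosage2[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r^2 of one SNP against the columns of a dosage matrix (complete data).
ld_r2_vec <- function(x, D) {
  suppressWarnings(as.vector(stats::cor(x, D, use = "pairwise.complete.obs"))^2)
}

#' Call cis eQTLs
#'
#' Retains cis-enumerated associations with p below the cis Bonferroni
#' threshold and flags, per probe, the SNP with the smallest p-value in
#' the window as the lead (ties broken by smaller position, then SNP id).
#' All significant SNP-probe pairs are kept; the lead flag identifies the
#' one reported cis-eQTL per probe.
#'
#' @param assocs association results restricted to cis pairs (output of
#'   [assoc_scan] on a cis enumeration).
#' @param threshold cis significance threshold (p <= threshold retained,
#'   full precision).
#' @param snp_map SNP map (snp_id, chrom, pos) for tie-breaking and
#'   window reporting.
#' @param annotation probe annotation, used to attach gene symbols.
#' @return data.frame of calls: association columns plus gene, class
#'   ("cis") and lead flag, ordered by probe then p.
#' @export
call_cis <- function(assocs, threshold, snp_map, annotation = NULL) {
  a <- assocs[!assocs$degenerate & assocs$p <= threshold, , drop = FALSE]
  if (nrow(a) == 0) {
    a$class <- character(0); a$lead <- logical(0); a$gene <- character(0)
    return(a)
  }
  a$pos <- snp_map$pos[match(a$snp_id, snp_map$snp_id)]
  a$gene <- if (is.null(annotation)) NA_character_ else
    annotation$gene[match(a$probe_id, annotation$probe_id)]
  a <- a[order(a$probe_id, a$p, a$pos, a$snp_id), , drop = FALSE]
  a$lead <- !duplicated(a$probe_id)
  a$class <- "cis"
  rownames(a) <- NULL
  a
}

#' Prune and clump trans eQTLs into genomic loci
#'
#' Two-step reduction of significant trans SNP-probe associations:
#' \enumerate{
#'   \item SNPs in high LD (r^2 > `r2`) with any significant cis SNP are
#'     dropped, since their trans signal may be shadowed by the cis locus.
#'   \item Remaining SNPs are greedily clumped: SNPs are processed in
#'     ascending order of their best p-value; a SNP joins the existing
#'     locus whose lead it correlates with at r^2 > `r2` (highest r^2
#'     wins if several), otherwise it founds a new locus and becomes its
#'     lead.
#' }
#'
#' @param assocs trans association results already thresholded at the
#'   trans Bonferroni threshold.
#' @param cis_calls significant cis calls (only their SNP ids are used).
#' @param geno the discovery [genotype_matrix] (LD reference).
#' @param r2 LD threshold (default 0.5).
#' @param annotation optional probe annotation to attach gene symbols.
#' @return list with `calls` (retained trans calls with locus_id and lead
#'   flag), `loci` (locus table: locus_id, lead_snp, n_snps, n_probes) and
#'   `n_dropped_cis_ld` (SNPs removed in step 1).
#' @export
prune_trans <- function(assocs, cis_calls, geno, r2 = 0.5, annotation = NULL) {
  a <- assocs[!assocs$degenerate, , drop = FALSE]
  empty <- function() {
    list(calls = cbind(a[0, , drop = FALSE],
                       data.frame(locus_id = character(0), lead = logical(0))),
         loci = data.frame(locus_id = character(0), lead_snp = character(0),
                           n_snps = integer(0), n_probes = integer(0),
                           stringsAsFactors = FALSE),
         n_dropped_cis_ld = 0L)
  }
  if (nrow(a) == 0) return(empty())
  D <- geno$dosage
  trans_snps <- unique(a$snp_id)
  cis_snps <- unique(cis_calls$snp_id)
  dropped <- character(0)
  if (length(cis_snps) > 0) {
    Dc <- D[, intersect(cis_snps, colnames(D)), drop = FALSE]
    if (ncol(Dc) > 0) {
      for (s in trans_snps) {
        r2s <- ld_r2_vec(D[, s], Dc)
        if (any(r2s > r2, na.rm = TRUE)) dropped <- c(dropped, s)
      }
    }
  }
  a <- a[!(a$snp_id %in% dropped), , drop = FALSE]
  if (nrow(a) == 0) { out <- empty(); out$n_dropped_cis_ld <- length(dropped); return(out) }
  # greedy clumping by ascending best p per SNP
  best <- stats::aggregate(p ~ snp_id, data = a, FUN = min)
  best <- best[order(best$p, best$snp_id), , drop = FALSE]
  leads <- character(0)
  locus_of <- character(0)
  for (s in best$snp_id) {
    assigned <- FALSE
    if (length(leads) > 0) {
      r2s <- ld_r2_vec(D[, s], D[, leads, drop = FALSE])
      if (any(r2s > r2, na.rm = TRUE)) {
        locus_of[s] <- leads[which.max(r2s)]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      leads <- c(leads, s)
      locus_of[s] <- s
    }
  }
  locus_ids <- stats::setNames(sprintf("locus%03d", seq_along(leads)), leads)
  a$locus_id <- locus_ids[locus_of[a$snp_id]]
  a$lead <- a$snp_id %in% leads
  a$class <- "trans"
  a$gene <- if (is.null(annotation)) NA_character_ else
    annotation$gene[match(a$probe_id, annotation$probe_id)]
  loci <- do.call(rbind, lapply(seq_along(leads), function(i) {
    m <- a[a$locus_id == locus_ids[i], , drop = FALSE]
    data.frame(locus_id = locus_ids[[i]], lead_snp = leads[i],
               n_snps = length(unique(m$snp_id)),
               n_probes = length(unique(m$probe_id)),
               stringsAsFactors = FALSE)
  }))
  rownames(a) <- NULL
  list(calls = a, loci = loci, n_dropped_cis_ld = length(dropped))
}

#' Summarize discovery-stage eQTL calls
#'
#' Headline counts of a discovery run: cis eQTLs (lead SNP-probe calls,
#' one per probe), trans SNP-probe associations, pruned trans loci, their
#' total (cis + trans loci), distinct cis genes, cis genes supported by
#' two or more transcript probes, and cis calls without a gene
#' assignment.
#'
#' @param cis_calls output of [call_cis].
#' @param trans_pruned output of [prune_trans].
#' @return list of counts: n_cis, n_trans_pairs, n_trans_loci, total,
#'   n_genes, n_multiprobe, n_unassigned.
#' @export
summarize_discovery <- function(cis_calls, trans_pruned) {
  leads <- cis_calls[isTRUE_vec(cis_calls$lead), , drop = FALSE]
  genes <- leads$gene[!is.na(leads$gene) & leads$gene != ""]
  gene_tab <- table(genes)
  n_trans_pairs <- nrow(trans_pruned$calls)
  n_trans_loci <- nrow(trans_pruned$loci)
  list(
    n_cis = nrow(leads),
    n_trans_pairs = n_trans_pairs,
    n_trans_loci = n_trans_loci,
    total = nrow(leads) + n_trans_loci,
    n_genes = length(gene_tab),
    n_multiprobe = sum(gene_tab >= 2),
    n_unassigned = sum(is.na(leads$gene) | leads$gene == "")
  )
}

isTRUE_vec <- function(x) !is.na(x) & x
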