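#' Detect master regulatory loci among trans eQTLs
#'
#' Counts, per trans locus, the distinct target genes among confirmed
#' trans calls (falling back to the probe id when no gene is assigned).
#' Loci reaching `min_targets` targets (default 5) are master regulatory
#' loci; loci reaching `multi_min` (default 2) are listed in the
#' multi-target report.
#'
#' @param trans_calls confirmed trans calls with snp_id, probe_id,
#'   locus_id and optionally gene.
#' @param loci locus table from [prune_trans] (locus_id, lead_snp).
#' @param min_targets master-locus threshold on distinct target genes.
#' @param multi_min multi-target report threshold.
#' @return list with `master` and `multi_target` data.frames (locus_id,
#'   lead_snp, target_count, targets) and `targets_by_locus` (named list
#'   of target vectors).
#' @export
detect_master_loci <- function(trans_calls, loci, min_targets = 5L,
                               multi_min = 2L) {
  tc <- as.data.frame(trans_calls)
  if (nrow(tc) == 0) {
    empty <- data.frame(locus_id = character(0), lead_snp = character(0),
                        target_count = integer(0), targets = character(0),
                        stringsAsFactors = FALSE)
    return(list(master = empty, multi_target = empty,
                targets_by_locus = list()))
  }
  gene <- if ("gene" %in% names(tc)) tc$gene else rep(NA_character_, nrow(tc))
  target <- ifelse(is.na(gene) | gene == "", tc$probe_id, gene)
  by_locus <- split(target, tc$locus_id)
  by_locus <- lapply(by_locus, function(x) sort(unique(x)))
  counts <- vapply(by_locus, length, integer(1))
  tab <- data.frame(
    locus_id = names(by_locus),
    lead_snp = loci$lead_snp[match(names(by_locus), loci$locus_id)],
    target_count = as.integer(counts),
    targets = vapply(by_locus, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$target_count, tab$locus_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(master = tab[tab$target_count >= min_targets, , drop = FALSE],
       multi_target = tab[tab$target_count >= multi_min, , drop = FALSE],
       targets_by_locus = by_locus)
}

#' Cross-study gene overlap percentage
#'
#' Fraction of this study's significant cis-eQTL genes that were also
#' annotated and significant in a compared study, as an integer
#' percentage: `round(100 * shared / denominator)` with half-away-from-
#' zero rounding. By default `shared` is the intersection size of the two
#' gene sets and `denominator` the size of this study's set, but both can
#' be supplied directly (published comparisons often restrict "shared" to
#' genes annotatable on both platforms).
#'
#' @param own_genes character vector of this study's significant genes.
#' @param other_genes compared study's significant genes.
#' @param shared number of genes annotated and significant in both.
#' @param denominator total significant genes in this study.
#' @return integer percentage.
#' @export
gene_overlap <- function(own_genes = NULL, other_genes = NULL,
                         shared = length(intersect(own_genes, other_genes)),
                         denominator = length(unique(own_genes))) {
  if (is.null(denominator) || length(denominator) != 1 || denominator <= 0) {
    stop("denominator must be a positive count")
  }
  percent_of(shared, denominator)
}

#' Triangular SNP-transcript-trait association
#'
#' Tests the three marginal edges of a putative SNP -> transcript ->
#' trait relationship with ordinary least squares on pairwise-complete
#' cases: transcript ~ SNP, trait ~ SNP and trait ~ transcript. The
#' verdict is positive when all three edges reach `alpha`. Only marginal
#' associations are reported; no mediation decomposition is attempted.
#'
#' @param geno a [genotype_matrix].
#' @param expr samples x probes expression matrix.
#' @param traits samples x traits matrix or data.frame.
#' @param snp_id,probe_id,trait column identifiers of the three vertices.
#' @param alpha per-edge significance level (default 0.05, nominal).
#' @return object of class `triangle_result`: the three edge statistics
#'   (each as returned by [regress_single]) and the `verdict` flag.
#' @export
triangular_test <- function(geno, expr, traits, snp_id, probe_id, trait,
                            alpha = 0.05) {
  expr <- as.matrix(expr); traits <- as.matrix(traits)
  if (!(snp_id %in% colnames(geno$dosage))) stop("missing SNP column: ", snp_id)
  if (!(probe_id %in% colnames(expr))) stop("missing probe column: ", probe_id)
  if (!(trait %in% colnames(traits))) stop("missing trait column: ", trait)
  g <- geno$dosage[, snp_id]
  e <- expr[, probe_id]
  y <- traits[, trait]
  edges <- list(
    snp_transcript = regress_single(g, e),
    snp_trait = regress_single(g, y),
    transcript_trait = regress_single(e, y)
  )
  ps <- vapply(edges, function(r) if (r$degenerate) NA_real_ else r$p,
               numeric(1))
  structure(list(
    snp_id = snp_id, probe_id = probe_id, trait = trait, alpha = alpha,
    edges = edges,
    verdict = !anyNA(ps) && all(ps <= alpha)
  ), class = "triangle_result")
}

#' @export
print.triangle_result <- function(x, ...) {
  cat(sprintf("triangle %s - %s - %s (alpha %.3g): %s\n", x$snp_id,
              x$probe_id, x$trait, x$alpha,
              if (x$verdict) "all edges significant" else "not supported"))
  for (nm in names(x$edges)) {
    e <- x$edges[[nm]]
    cat(sprintf("  %-17s beta % .4f  se %.4f  p %.3g  n %d\n",
                nm, e$beta, e$se, e$p, e$n))
  }
  invisible(x)
}

#' Join calls against a phenotype annotation table
#'
#' Generic intersection of eQTL calls with a user-supplied SNP-phenotype
#' table (e.g. curated GWAS or metabolite-QTL hits): returns the calls
#' whose SNP carries at least one phenotype annotation, with phenotypes
#' attached.
#'
#' @param calls data.frame with a snp_id column.
#' @param snp_phenotypes data.frame with columns snp_id, phenotype.
#' @return merged data.frame (inner join on snp_id).
#' @export
annotate_phenotypes <- function(calls, snp_phenotypes) {
  stopifnot(all(c("snp_id", "phenotype") %in% names(snp_phenotypes)))
  merge(as.data.frame(calls), snp_phenotypes, by = "snp_id")
}
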