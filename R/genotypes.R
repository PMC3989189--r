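#' Genotype matrix container
#'
#' Couples a samples x SNPs additive dosage matrix (counts of the ALT
#' allele, values 0/1/2 or NA for missing calls) with its SNP map. All
#' positions are 0-based internally.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns (colnames = SNP ids), entries in \{0,1,2,NA\}.
#' @param map data.frame with columns snp_id, chrom, pos, ref, alt, one row
#'   per dosage column, in column order.
#' @return an object of class `genotype_matrix` with elements `dosage` and
#'   `map`.
#' @export
genotype_matrix <- function(dosage, map) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  map <- as.data.frame(map)
  need <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(map))) {
    stop("map must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(map) != ncol(dosage)) {
    stop("map rows (", nrow(map), ") must match dosage columns (",
         ncol(dosage), ")")
  }
  if (ncol(dosage) > 0) {
    if (is.null(colnames(dosage))) colnames(dosage) <- map$snp_id
    if (!identical(colnames(dosage), as.character(map$snp_id))) {
      stop("dosage column names must equal map$snp_id in order")
    }
    bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
    if (length(bad) > 0) stop("dosage entries must be 0, 1, 2 or NA")
  }
  if (is.null(rownames(dosage)) && nrow(dosage) > 0) {
    rownames(dosage) <- sprintf("S%04d", seq_len(nrow(dosage)))
  }
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Per-SNP summary statistics
#'
#' Minor allele frequency (on non-missing calls), call rate and
#' Hardy-Weinberg exact-test p-value for every SNP of a genotype matrix.
#'
#' @param geno a `genotype_matrix`.
#' @return data.frame with columns snp_id, chrom, pos, ref, alt, maf,
#'   call_rate, hwe_p.
#' @export
snp_stats <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  n <- nrow(d)
  n_obs <- colSums(!is.na(d))
  alt_count <- colSums(d, na.rm = TRUE)
  af <- ifelse(n_obs > 0, alt_count / (2 * n_obs), NA_real_)
  maf <- pmin(af, 1 - af)
  n_het <- colSums(d == 1, na.rm = TRUE)
  n_hom_alt <- colSums(d == 2, na.rm = TRUE)
  n_hom_ref <- n_obs - n_het - n_hom_alt
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    hwe_exact_test(n_hom_ref[j], n_het[j], n_hom_alt[j])
  }, numeric(1))
  data.frame(
    snp_id = geno$map$snp_id, chrom = geno$map$chrom, pos = geno$map$pos,
    ref = geno$map$ref, alt = geno$map$alt,
    maf = maf, call_rate = n_obs / n, hwe_p = hwe_p,
    stringsAsFactors = FALSE
  )
}

# Subset a genotype matrix by SNP index or id, keeping map in sync.
subset_snps <- function(geno, keep) {
  if (is.character(keep)) keep <- match(keep, geno$map$snp_id)
  genotype_matrix(geno$dosage[, keep, drop = FALSE],
                  geno$map[keep, , drop = FALSE])
}
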