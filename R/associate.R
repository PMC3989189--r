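#' Single SNP-probe additive regression
#'
#' Ordinary least squares of an expression (or other quantitative) vector
#' on an additive dosage vector, on pairwise-complete cases. Returns the
#' slope per copy of the counted (ALT) allele, its standard error, the
#' t-statistic on n-2 degrees of freedom and the two-sided p-value.
#' Degenerate fits (constant dosage or fewer than 3 complete pairs) are
#' flagged rather than raising; perfect fits have their p-value floored at
#' `p_floor` and carry the `p_floored` flag.
#'
#' @param dosage numeric dosage vector.
#' @param y numeric response vector of the same length.
#' @param p_floor smallest reportable p-value (default 1e-300).
#' @return list with n, beta, se, t, p, degenerate, p_floored.
#' @export
regress_single <- function(dosage, y, p_floor = 1e-300) {
  if (length(dosage) != length(y)) stop("vectors differ in length")
  ok <- !is.na(dosage) & !is.na(y)
  x <- dosage[ok]; yy <- y[ok]
  n <- length(x)
  degen <- list(n = n, beta = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, degenerate = TRUE, p_floored = FALSE)
  if (n < 3) return(degen)
  sxx <- sum((x - mean(x))^2)
  if (sxx < .Machine$double.eps * n) return(degen)
  sxy <- sum((x - mean(x)) * (yy - mean(yy)))
  syy <- sum((yy - mean(yy))^2)
  beta <- sxy / sxx
  ssr <- max(syy - beta * sxy, 0)
  df <- n - 2
  floored <- FALSE
  if (ssr <= .Machine$double.eps * max(syy, 1)) {
    # perfect fit: zero residual variance
    se <- 0
    tval <- Inf * sign(beta)
    p <- p_floor
    floored <- TRUE
  } else {
    se <- sqrt(ssr / df / sxx)
    tval <- beta / se
    p <- 2 * stats::pt(-abs(tval), df)
    if (p < p_floor) { p <- p_floor; floored <- TRUE }
  }
  list(n = n, beta = beta, se = se, t = tval, p = p,
       degenerate = FALSE, p_floored = floored)
}

# Vectorized scan statistics for one SNP against an expression matrix,
# pairwise-complete. Returns a data.frame over probes.
scan_one_snp <- function(x, E, p_floor = 1e-300) {
  okx <- !is.na(x)
  Es <- E[okx, , drop = FALSE]
  xs <- x[okx]
  M <- !is.na(Es)
  E0 <- Es; E0[!M] <- 0
  n <- colSums(M)
  sum_x <- colSums(M * xs)
  sum_x2 <- colSums(M * xs^2)
  sum_y <- colSums(E0)
  sum_y2 <- colSums(E0^2)
  sum_xy <- colSums(E0 * xs)
  finalize_scan(n, sum_x, sum_x2, sum_y, sum_y2, sum_xy, p_floor)
}

finalize_scan <- function(n, sum_x, sum_x2, sum_y, sum_y2, sum_xy, p_floor) {
  sxx <- sum_x2 - sum_x^2 / n
  sxy <- sum_xy - sum_x * sum_y / n
  syy <- sum_y2 - sum_y^2 / n
  degenerate <- n < 3 | sxx < .Machine$double.eps * pmax(n, 1)
  beta <- ifelse(degenerate, NA_real_, sxy / sxx)
  ssr <- pmax(syy - beta * sxy, 0)
  df <- n - 2
  perfect <- !degenerate & ssr <= .Machine$double.eps * pmax(syy, 1)
  se <- ifelse(degenerate, NA_real_, sqrt(ssr / df / sxx))
  se[perfect] <- 0
  tval <- ifelse(se > 0, beta / se, ifelse(perfect, Inf * sign(beta), NA_real_))
  p <- ifelse(degenerate, NA_real_, 2 * stats::pt(-abs(tval), df))
  p[perfect] <- 0
  floored <- !degenerate & p < p_floor
  p <- ifelse(floored, p_floor, p)
  data.frame(n = n, beta = beta, se = se, t = tval, p = p,
             degenerate = degenerate, p_floored = floored)
}

#' Mass SNP-probe association scan
#'
#' Runs the additive linear regression of [regress_single] over many
#' SNP-probe pairs: all pairs, an explicit pair list, or the cis pairs
#' within a window of each probe's transcription unit. Execution is
#' blockwise/vectorized but numerically equal to calling [regress_single]
#' per pair; missing genotypes or expression values are dropped pairwise,
#' so n can vary between pairs.
#'
#' All-pairs scans above `pair_budget` are refused unless `force = TRUE`,
#' as a guard against accidental genome-scale memory use.
#'
#' @param geno a [genotype_matrix].
#' @param expr samples x probes expression matrix (same sample order).
#' @param pairs optional data.frame (snp_id, probe_id) restricting the
#'   scan; overrides `mode`.
#' @param mode "all" or "cis" (requires `annotation`).
#' @param annotation probe annotation (probe_id, gene, chrom, tx_start,
#'   tx_end) for cis enumeration.
#' @param flank cis window half-width in bp.
#' @param p_floor smallest reportable p-value.
#' @param pair_budget maximum number of pairs without `force`.
#' @param force allow scans above the budget.
#' @return data.frame with snp_id, probe_id, n, beta, se, t, p,
#'   effect_allele, degenerate, p_floored.
#' @export
assoc_scan <- function(geno, expr, pairs = NULL, mode = c("all", "cis"),
                       annotation = NULL, flank = 500000L,
                       p_floor = 1e-300, pair_budget = 5e7, force = FALSE) {
  stopifnot(inherits(geno, "genotype_matrix"))
  expr <- as.matrix(expr)
  if (nrow(expr) != nrow(geno$dosage)) {
    stop("expression and genotypes have different sample counts")
  }
  mode <- match.arg(mode)
  D <- geno$dosage
  alt <- geno$map$alt[match(colnames(D), geno$map$snp_id)]
  if (is.null(pairs) && mode == "cis") {
    if (is.null(annotation)) stop("cis mode requires a probe annotation")
    pairs <- enumerate_cis_pairs(geno$map, annotation, flank)$pairs
  }
  if (is.null(pairs)) {
    n_pairs <- as.numeric(ncol(D)) * ncol(expr)
    if (n_pairs > pair_budget && !force) {
      stop("all-pairs scan of ", format(n_pairs, big.mark = ","),
           " pairs exceeds the pair budget; use force = TRUE")
    }
    if (anyNA(D) || anyNA(expr)) {
      res <- lapply(seq_len(ncol(D)), function(j) {
        r <- scan_one_snp(D[, j], expr, p_floor)
        cbind(snp_id = colnames(D)[j], probe_id = colnames(expr), r,
              stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, res)
    } else {
      out <- scan_dense(D, expr, p_floor)
    }
  } else {
    pairs <- as.data.frame(pairs)
    si <- match(pairs$snp_id, colnames(D))
    pi <- match(pairs$probe_id, colnames(expr))
    if (anyNA(si)) stop("unknown snp_id in pair list")
    if (anyNA(pi)) stop("unknown probe_id in pair list")
    if (nrow(pairs) == 0) {
      out <- empty_scan_result()
      out$effect_allele <- character(0)
      return(out)
    }
    res <- lapply(seq_len(nrow(pairs)), function(k) {
      as.data.frame(regress_single(D[, si[k]], expr[, pi[k]], p_floor))
    })
    out <- cbind(snp_id = pairs$snp_id, probe_id = pairs$probe_id,
                 do.call(rbind, res), stringsAsFactors = FALSE)
  }
  out$effect_allele <- alt[match(out$snp_id, colnames(D))]
  rownames(out) <- NULL
  out
}

# Dense no-missing path: all statistics from three cross-products.
scan_dense <- function(D, E, p_floor) {
  n <- nrow(D)
  S <- ncol(D); P <- ncol(E)
  sum_x <- colSums(D); sum_x2 <- colSums(D^2)
  sum_y <- colSums(E); sum_y2 <- colSums(E^2)
  XY <- crossprod(D, E)  # S x P
  grid <- expand.grid(s = seq_len(S), p = seq_len(P))
  r <- finalize_scan(rep(n, S * P),
                     sum_x[grid$s], sum_x2[grid$s],
                     sum_y[grid$p], sum_y2[grid$p],
                     as.vector(XY), p_floor)
  cbind(snp_id = colnames(D)[grid$s], probe_id = colnames(E)[grid$p], r,
        stringsAsFactors = FALSE)
}

empty_scan_result <- function() {
  data.frame(snp_id = character(0), probe_id = character(0),
             n = integer(0), beta = numeric(0), se = numeric(0),
             t = numeric(0), p = numeric(0), degenerate = logical(0),
             p_floored = logical(0), stringsAsFactors = FALSE)
}

#' Minimum p-value of an all-pairs scan
#'
#' Memory-light helper for null simulations: computes the smallest
#' two-sided p-value over all SNP-probe pairs without materializing the
#' per-pair result table. Requires complete data.
#'
#' @param geno a [genotype_matrix] without missing calls.
#' @param expr complete expression matrix.
#' @return smallest p-value across all pairs (degenerate SNPs skipped).
#' @export
scan_min_p <- function(geno, expr) {
  D <- geno$dosage; E <- as.matrix(expr)
  if (anyNA(D) || anyNA(E)) stop("scan_min_p requires complete data")
  n <- nrow(D)
  Ds <- scale(D); Es <- scale(E)
  keep <- !is.na(colSums(Ds)) & apply(D, 2, stats::var) > 0
  r <- crossprod(Ds[, keep, drop = FALSE], Es) / (n - 1)
  r2max <- max(r^2, na.rm = TRUE)
  tmax <- sqrt(r2max * (n - 2) / max(1 - r2max, .Machine$double.eps))
  2 * stats::pt(-tmax, n - 2)
}

#' Enumerate cis SNP-probe pairs
#'
#' A pair is cis when the SNP lies on the probe's chromosome within
#' `flank` bp of the transcription unit, boundaries inclusive:
#' `tx_start - flank <= pos <= tx_end + flank` (window floor clamped at 0).
#' The returned count is the Bonferroni denominator for the cis scan.
#'
#' @param snp_map data.frame with snp_id, chrom, pos.
#' @param annotation probe annotation with probe_id, chrom, tx_start,
#'   tx_end; probes with missing coordinates are excluded and counted.
#' @param flank window half-width in bp (default 500 kb).
#' @return list with `pairs` (data.frame snp_id, probe_id), `n_pairs` and
#'   `n_probes_unmapped`.
#' @export
enumerate_cis_pairs <- function(snp_map, annotation, flank = 500000L) {
  snp_map <- as.data.frame(snp_map)
  ann <- as.data.frame(annotation)
  unmapped <- is.na(ann$chrom) | is.na(ann$tx_start) | is.na(ann$tx_end)
  ann <- ann[!unmapped, , drop = FALSE]
  parts <- lapply(split(seq_len(nrow(ann)), ann$chrom), function(ix) {
    snps <- snp_map[snp_map$chrom == ann$chrom[ix[1]], , drop = FALSE]
    if (nrow(snps) == 0) return(NULL)
    do.call(rbind, lapply(ix, function(i) {
      lo <- max(ann$tx_start[i] - flank, 0)
      hi <- ann$tx_end[i] + flank
      hit <- snps$pos >= lo & snps$pos <= hi
      if (!any(hit)) return(NULL)
      data.frame(snp_id = snps$snp_id[hit], probe_id = ann$probe_id[i],
                 stringsAsFactors = FALSE)
    }))
  })
  pairs <- do.call(rbind, parts)
  if (is.null(pairs)) {
    pairs <- data.frame(snp_id = character(0), probe_id = character(0),
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_probes_unmapped = sum(unmapped))
}
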