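#' Principal components of an expression matrix
#'
#' Computes the top-k principal components of the probe-standardized
#' expression matrix (each probe centered; scaled to unit SD when
#' `scale = TRUE`, the default, mirroring array-normalized data). The
#' returned component vectors are the orthonormal left singular vectors
#' (samples x k). The sign of each component is fixed so that its
#' largest-magnitude entry is positive, making the decomposition
#' deterministic.
#'
#' @param expr samples x probes numeric matrix.
#' @param k number of components; must not exceed the numerical rank.
#' @param scale standardize probes to unit SD before decomposition.
#' @return object of class `pc_basis`: `components` (samples x k,
#'   orthonormal), `explained` (variance fractions, non-increasing),
#'   `center`, `scale` (per-probe vectors), `samples`.
#' @export
compute_pcs <- function(expr, k, scale = TRUE) {
  expr <- as.matrix(expr)
  k <- as.integer(k)
  if (k < 0) stop("k must be non-negative")
  if (k > min(dim(expr))) stop("k exceeds min(samples, probes)")
  ctr <- colMeans(expr)
  scl <- rep(1, ncol(expr))
  if (scale && ncol(expr) > 0) {
    scl <- apply(expr, 2, stats::sd)
    scl[!is.finite(scl) | scl < .Machine$double.eps] <- 1
  }
  x <- sweep(sweep(expr, 2, ctr), 2, scl, `/`)
  if (k == 0 || nrow(expr) == 0) {
    return(structure(list(
      components = matrix(0, nrow(expr), 0), explained = numeric(0),
      center = ctr, scale = scl, samples = rownames(expr)
    ), class = "pc_basis"))
  }
  sv <- svd(x, nu = min(dim(x)), nv = 0)
  rank <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (k > rank) stop("k (", k, ") exceeds the rank (", rank, ") of the matrix")
  u <- sv$u[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  rownames(u) <- rownames(expr)
  structure(list(
    components = u,
    explained = (sv$d[seq_len(k)]^2) / sum(sv$d^2),
    center = ctr, scale = scl, samples = rownames(expr)
  ), class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf("pc_basis: %d components over %d samples\n",
              ncol(x$components), nrow(x$components)))
  invisible(x)
}

#' Residualize expression on a principal-component basis
#'
#' Removes the span of the basis components from every (centered) probe
#' column: the residual of a linear model with expression as dependent and
#' the principal components as independent variables. Residual columns are
#' orthogonal to every component and per-probe variance cannot increase.
#' The operation is idempotent.
#'
#' @param expr samples x probes matrix over the same samples as `basis`.
#' @param basis a `pc_basis` from [compute_pcs] (possibly with columns
#'   dropped via [drop_pcs]).
#' @return residual expression matrix (centered).
#' @export
residualize <- function(expr, basis) {
  expr <- as.matrix(expr)
  stopifnot(inherits(basis, "pc_basis"))
  if (nrow(expr) != nrow(basis$components) ||
      (!is.null(basis$samples) && !is.null(rownames(expr)) &&
       !identical(rownames(expr), basis$samples))) {
    stop("expression samples do not match the PC basis")
  }
  x <- sweep(expr, 2, colMeans(expr))
  u <- basis$components
  if (ncol(u) == 0) return(x)
  x - u %*% crossprod(u, x)
}

#' Drop selected components from a basis
#'
#' @param basis a `pc_basis`.
#' @param drop integer indices of components to remove.
#' @return the reduced `pc_basis`.
#' @export
drop_pcs <- function(basis, drop) {
  if (length(drop) == 0) return(basis)
  basis$components <- basis$components[, -drop, drop = FALSE]
  basis$explained <- basis$explained[-drop]
  basis
}

#' Flag principal components associated with a SNP
#'
#' Regresses each component on the SNP dosage and flags components with
#' p-value below `alpha`. Used at replication time, where components
#' associated with the SNP of interest are excluded before
#' residualization so genetic signal is not regressed away.
#'
#' @param basis a `pc_basis`.
#' @param dosage dosage vector over the basis samples.
#' @param alpha nominal significance level (default 0.05).
#' @return integer indices of flagged components (possibly empty).
#' @export
snp_associated_pcs <- function(basis, dosage, alpha = 0.05) {
  stopifnot(inherits(basis, "pc_basis"))
  if (length(dosage) != nrow(basis$components)) {
    stop("dosage length does not match the PC basis")
  }
  if (alpha <= 0) return(integer(0))
  ok <- !is.na(dosage)
  if (stats::var(dosage[ok]) == 0) {
    warning("constant dosage: no PC flagged")
    return(integer(0))
  }
  which(vapply(seq_len(ncol(basis$components)), function(j) {
    r <- regress_single(dosage, basis$components[, j])
    !r$degenerate && r$p < alpha
  }, logical(1)))
}

#' Sweep over numbers of removed principal components
#'
#' Re-runs an association scan over a fixed set of SNP-probe pairs after
#' removing k = 0 (the uncorrected data), then each value of `grid`,
#' principal components, reporting the mean standard error, mean absolute
#' effect size and the number of significant cis and trans pairs at the
#' supplied thresholds. The table supports choosing the number of
#' components to remove by inspection; no automatic selection is applied.
#'
#' @param expr samples x probes expression matrix.
#' @param geno a [genotype_matrix] on the same samples.
#' @param grid PC counts to evaluate (default `seq(5, 100, by = 5)`,
#'   truncated to the matrix rank).
#' @param cis_pairs,trans_pairs data.frames (snp_id, probe_id) defining
#'   which scanned pairs count as cis and trans.
#' @param cis_threshold,trans_threshold significance thresholds applied to
#'   the respective pair sets.
#' @return data.frame with columns k, mean_se, mean_abs_beta,
#'   n_significant_cis, n_significant_trans.
#' @export
pc_sweep <- function(expr, geno, grid = seq(5L, 100L, by = 5L),
                     cis_pairs = NULL, trans_pairs = NULL,
                     cis_threshold = 1e-8, trans_threshold = 1e-11) {
  expr <- as.matrix(expr)
  ks <- unique(c(0L, as.integer(grid)))
  out <- lapply(ks, function(k) {
    basis <- compute_pcs(expr, k)
    res <- residualize(expr, basis)
    pairs <- rbind(
      if (!is.null(cis_pairs)) cbind(cis_pairs, class = "cis"),
      if (!is.null(trans_pairs)) cbind(trans_pairs, class = "trans")
    )
    a <- assoc_scan(geno, res, pairs = pairs[, c("snp_id", "probe_id")])
    a$class <- pairs$class[match(paste(a$snp_id, a$probe_id),
                                 paste(pairs$snp_id, pairs$probe_id))]
    ok <- !a$degenerate
    data.frame(
      k = k,
      mean_se = mean(a$se[ok]),
      mean_abs_beta = mean(abs(a$beta[ok])),
      n_significant_cis = sum(ok & a$class == "cis" & a$p <= cis_threshold),
      n_significant_trans = sum(ok & a$class == "trans" & a$p <= trans_threshold)
    )
  })
  do.call(rbind, out)
}
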