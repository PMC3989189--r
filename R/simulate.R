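#' Simulation configuration for synthetic eQTL cohorts
#'
#' Describes a cohort with the statistical structure a whole-blood eQTL
#' analysis assumes: Hardy-Weinberg genotypes with common alleles, LD
#' blocks with tunable decay, additive cis effects planted near their
#' target probes, trans hotspots hitting sets of distant probes, latent
#' expression confounders and simple trait models. Effect sizes are in SD
#' units of the pre-genetic expression signal (each probe is standardized
#' before the genetic effects are added).
#'
#' Genomic layout: SNPs are placed on chromosome "1" at `snp_spacing` bp
#' intervals; probes default to chromosome "2" (so every SNP-probe pair is
#' trans) except that the target probe of each planted cis effect is moved
#' next to its SNP on chromosome "1", inside the cis window.
#'
#' @param n_individuals,n_snps,n_probes cohort dimensions.
#' @param maf_range range the per-SNP minor allele frequency is drawn from,
#'   uniformly; both ends in (0, 0.5].
#' @param ld_block_size number of consecutive SNPs per LD block.
#' @param ld_decay lag-1 haplotype correlation within a block, in [0,1);
#'   0 gives independent SNPs.
#' @param cis_effects list of `list(snp = i, probe = j, beta = b)`.
#' @param trans_hotspots list of `list(snp = i, probes = js, betas = bs)`
#'   (`betas` may be length 1, recycled).
#' @param n_confounders number of latent expression factors.
#' @param confounder_sd SD of the latent factor scores.
#' @param noise_sd SD of the i.i.d. probe noise; must be positive unless
#'   explicitly exercising the noiseless limit.
#' @param trait_models list of `list(name, probe = j | snp = i, beta, noise_sd)`.
#' @param snp_spacing distance between adjacent SNPs in bp.
#' @param seed integer seed; all generators derive their streams from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 200L,
                       n_snps = 100L,
                       n_probes = 50L,
                       maf_range = c(0.1, 0.5),
                       ld_block_size = 10L,
                       ld_decay = 0.8,
                       cis_effects = list(),
                       trans_hotspots = list(),
                       n_confounders = 0L,
                       confounder_sd = 1,
                       noise_sd = 1,
                       trait_models = list(),
                       snp_spacing = 20000L,
                       seed = 1L) {
  if (n_individuals < 0) stop_config("n_individuals", "must be non-negative")
  if (n_snps < 0) stop_config("n_snps", "must be non-negative")
  if (n_probes < 0) stop_config("n_probes", "must be non-negative")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_config("maf_range", "must be an increasing pair in (0, 0.5]")
  }
  if (ld_block_size < 1) stop_config("ld_block_size", "must be >= 1")
  if (ld_decay < 0 || ld_decay >= 1) stop_config("ld_decay", "must lie in [0,1)")
  if (noise_sd < 0) stop_config("noise_sd", "must be non-negative")
  if (confounder_sd <= 0) stop_config("confounder_sd", "must be positive")
  if (n_confounders < 0) stop_config("n_confounders", "must be non-negative")
  check_pair <- function(e, what) {
    s <- e$snp
    ps <- e$probe %||% e$probes
    if (is.null(s) || any(s < 1) || any(s > n_snps)) {
      stop_config(what, sprintf("snp index out of bounds (n_snps = %d)", n_snps))
    }
    if (is.null(ps) || any(ps < 1) || any(ps > n_probes)) {
      stop_config(what, sprintf("probe index out of bounds (n_probes = %d)", n_probes))
    }
  }
  for (e in cis_effects) check_pair(e, "cis_effects")
  for (e in trans_hotspots) check_pair(e, "trans_hotspots")
  for (tm in trait_models) {
    if (is.null(tm$name)) stop_config("trait_models", "needs a name per trait")
    if (!is.null(tm$probe) && (tm$probe < 1 || tm$probe > n_probes)) {
      stop_config("trait_models", "probe index out of bounds")
    }
    if (!is.null(tm$snp) && (tm$snp < 1 || tm$snp > n_snps)) {
      stop_config("trait_models", "snp index out of bounds")
    }
    if (is.null(tm$probe) && is.null(tm$snp)) {
      stop_config("trait_models", "needs a probe or snp source")
    }
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_probes = as.integer(n_probes), maf_range = as.numeric(maf_range),
    ld_block_size = as.integer(ld_block_size), ld_decay = ld_decay,
    cis_effects = cis_effects, trans_hotspots = trans_hotspots,
    n_confounders = as.integer(n_confounders), confounder_sd = confounder_sd,
    noise_sd = noise_sd, trait_models = trait_models,
    snp_spacing = as.integer(snp_spacing), seed = as.integer(seed)
  ), class = "sim_config")
}

snp_ids_of <- function(config) {
  if (config$n_snps == 0) character(0) else sprintf("snp%05d", seq_len(config$n_snps))
}
probe_ids_of <- function(config) {
  if (config$n_probes == 0) character(0) else sprintf("probe%05d", seq_len(config$n_probes))
}

#' Simulate Hardy-Weinberg genotypes with LD block structure
#'
#' Each SNP's minor allele frequency is drawn uniformly from
#' `config$maf_range`. The two haplotypes of an individual are generated
#' independently (hence HWE holds exactly at each SNP); within a haplotype
#' the alleles follow a Gaussian copula whose latent process is AR(1) with
#' coefficient `ld_decay` inside each LD block and independent across
#' blocks, so adjacent SNPs in a block are correlated and correlation
#' decays geometrically with distance.
#'
#' Draw order (fixed for reproducibility): MAFs first, then the latent
#' normals of haplotype one, then haplotype two.
#'
#' @param config a `sim_config`.
#' @return a [genotype_matrix]; SNPs sit on chromosome "1" at
#'   `snp_spacing` bp intervals.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  set.seed(derive_seed(config$seed, 0))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  dosage <- matrix(0L, nrow = n, ncol = m)
  if (n > 0 && m > 0) {
    thr <- stats::qnorm(maf)
    rho <- config$ld_decay
    block <- ((seq_len(m) - 1L) %/% config$ld_block_size) + 1L
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), nrow = n, ncol = m)
      if (rho > 0 && m > 1) {
        for (j in 2:m) {
          if (block[j] == block[j - 1L]) {
            z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
          }
        }
      }
      # allele is ALT iff the latent normal falls below the MAF quantile
      sweep(z, 2, thr, `<`) * 1L
    }
    dosage <- hap() + hap()
  }
  ids <- snp_ids_of(config)
  colnames(dosage) <- ids
  if (n > 0) rownames(dosage) <- sprintf("S%04d", seq_len(n))
  map <- data.frame(
    snp_id = ids, chrom = rep("1", m),
    pos = if (m == 0) integer(0) else config$snp_spacing * seq_len(m),
    ref = rep("A", m), alt = rep("G", m),
    maf = maf, stringsAsFactors = FALSE
  )
  genotype_matrix(dosage, map)
}

# Probe annotation implied by the planted layout (0-based half-open).
probe_annotation_of <- function(config, geno) {
  p <- config$n_probes
  ids <- probe_ids_of(config)
  ann <- data.frame(
    probe_id = ids,
    gene = if (p == 0) character(0) else sprintf("GENE%04d", seq_len(p)),
    chrom = rep("2", p),
    tx_start = if (p == 0) integer(0) else 1000000L * seq_len(p),
    tx_end = if (p == 0) integer(0) else 1000000L * seq_len(p) + 10000L,
    strand = rep("+", p),
    stringsAsFactors = FALSE
  )
  for (e in config$cis_effects) {
    pos <- geno$map$pos[e$snp]
    ann$chrom[e$probe] <- geno$map$chrom[e$snp]
    ann$tx_start[e$probe] <- pos + 1000L
    ann$tx_end[e$probe] <- pos + 11000L
  }
  ann
}

#' Simulate expression with planted genetic effects and confounders
#'
#' Builds each probe as latent-confounder signal plus Gaussian noise,
#' standardizes it (mean 0, SD 1 per probe, mirroring upstream array
#' normalization) and then adds the planted additive genetic effects
#' `beta * centered dosage` for every configured cis effect and trans
#' hotspot, so betas read in SD units. Returns the expression matrix, the
#' truth ledger of planted effects and the probe annotation implied by the
#' planted layout.
#'
#' @param geno a [genotype_matrix] from [simulate_genotypes].
#' @param config the same `sim_config`.
#' @param truth optional truth ledger from a previous call; when given, its
#'   confounder loadings and planted effect map are reused (used for
#'   replication cohorts), only factor scores and noise are redrawn.
#' @param seed_offset offset added to `config$seed` for this stage's RNG
#'   stream (default 1; genotypes use offset 0, traits 2).
#' @return list with elements `expression` (samples x probes matrix),
#'   `truth` (class `sim_truth`) and `annotation` (probe annotation
#'   data.frame, 0-based half-open tx intervals).
#' @export
simulate_expression <- function(geno, config, truth = NULL, seed_offset = 1) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(config, "sim_config"))
  if (nrow(geno$dosage) != config$n_individuals) {
    stop_config("n_individuals", "does not match the genotype matrix")
  }
  n <- config$n_individuals
  p <- config$n_probes
  q <- config$n_confounders
  set.seed(derive_seed(config$seed, seed_offset))
  loadings <- if (!is.null(truth)) {
    truth$confounder_loadings
  } else if (q > 0) {
    matrix(stats::rnorm(p * q), nrow = p, ncol = q,
           dimnames = list(probe_ids_of(config), NULL))
  } else {
    matrix(0, nrow = p, ncol = 0, dimnames = list(probe_ids_of(config), NULL))
  }
  expr <- matrix(0, nrow = n, ncol = p,
                 dimnames = list(rownames(geno$dosage), probe_ids_of(config)))
  if (n > 0 && p > 0) {
    base <- matrix(stats::rnorm(n * p, sd = max(config$noise_sd, 0)), n, p)
    if (ncol(loadings) > 0) {
      scores <- matrix(stats::rnorm(n * ncol(loadings), sd = config$confounder_sd),
                       n, ncol(loadings))
      base <- base + scores %*% t(loadings)
    }
    # standardize the pre-genetic signal so planted betas are SD units;
    # degenerate (constant) probes are only centered
    mu <- colMeans(base)
    sdv <- apply(base, 2, stats::sd)
    sdv[sdv < .Machine$double.eps] <- 1
    expr <- sweep(sweep(base, 2, mu), 2, sdv, `/`)
    dimnames(expr) <- list(rownames(geno$dosage), probe_ids_of(config))
  }
  planted <- plant_map(config)
  if (nrow(planted) > 0 && n > 0) {
    for (k in seq_len(nrow(planted))) {
      g <- geno$dosage[, planted$snp_index[k]]
      expr[, planted$probe_index[k]] <- expr[, planted$probe_index[k]] +
        planted$beta[k] * (g - mean(g, na.rm = TRUE))
    }
  }
  ann <- probe_annotation_of(config, geno)
  tr <- structure(list(
    planted_cis = planted[planted$class == "cis",
                          c("snp_id", "probe_id", "beta"), drop = FALSE],
    planted_trans = planted[planted$class == "trans",
                            c("snp_id", "probe_id", "beta"), drop = FALSE],
    confounder_loadings = loadings,
    trait_edges = trait_edge_table(config)
  ), class = "sim_truth")
  list(expression = expr, truth = tr, annotation = ann)
}

# Flatten the configured effects into one planted-pair table.
plant_map <- function(config) {
  rows <- list()
  sid <- snp_ids_of(config); pid <- probe_ids_of(config)
  for (e in config$cis_effects) {
    rows[[length(rows) + 1L]] <- data.frame(
      snp_index = e$snp, probe_index = e$probe, beta = e$beta,
      snp_id = sid[e$snp], probe_id = pid[e$probe], class = "cis",
      stringsAsFactors = FALSE)
  }
  for (e in config$trans_hotspots) {
    betas <- rep(e$betas %||% e$beta, length.out = length(e$probes))
    rows[[length(rows) + 1L]] <- data.frame(
      snp_index = e$snp, probe_index = e$probes, beta = betas,
      snp_id = sid[e$snp], probe_id = pid[e$probes], class = "trans",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(snp_index = integer(0), probe_index = integer(0),
                      beta = numeric(0), snp_id = character(0),
                      probe_id = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[out$beta != 0, , drop = FALSE]
}

trait_edge_table <- function(config) {
  if (length(config$trait_models) == 0) {
    return(data.frame(trait = character(0), source = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(config$trait_models, function(tm) {
    src <- if (!is.null(tm$probe)) probe_ids_of(config)[tm$probe]
           else snp_ids_of(config)[tm$snp]
    data.frame(trait = tm$name, source = src, beta = tm$beta,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate traits from expression or genotype sources
#'
#' Each configured trait is `beta * source column + Gaussian noise`, the
#' source being either a probe's expression or a SNP's dosage.
#'
#' @param expr expression matrix (samples x probes) from
#'   [simulate_expression].
#' @param geno the cohort's [genotype_matrix].
#' @param config the `sim_config` whose `trait_models` are realized.
#' @return samples x traits numeric matrix (0 columns when no trait models).
#' @export
simulate_traits <- function(expr, geno, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(expr)
  set.seed(derive_seed(config$seed, 2))
  tms <- config$trait_models
  out <- matrix(numeric(0), nrow = n, ncol = 0)
  rownames(out) <- rownames(expr)
  for (tm in tms) {
    src <- if (!is.null(tm$probe)) {
      expr[, tm$probe]
    } else {
      geno$dosage[, tm$snp]
    }
    y <- tm$beta * src + stats::rnorm(n, sd = tm$noise_sd %||% 1)
    out <- cbind(out, y)
    colnames(out)[ncol(out)] <- tm$name
  }
  out
}

#' Simulate an independent replication cohort from the same truth
#'
#' Draws new individuals under the same configuration and planted effect
#' map (betas and confounder loadings reused from `truth`), so effect
#' signs carry over while genotype and noise realizations are independent.
#'
#' @param truth `sim_truth` from a previous [simulate_expression] call.
#' @param config the originating `sim_config`.
#' @param new_seed seed for the replication cohort's RNG streams.
#' @return list with `genotypes`, `expression`, `annotation` and `truth`
#'   (the ledger passed in, unchanged).
#' @export
simulate_replication_cohort <- function(truth, config, new_seed) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  cfg2 <- config
  cfg2$seed <- as.integer(new_seed)
  geno <- simulate_genotypes(cfg2)
  sim <- simulate_expression(geno, cfg2, truth = truth)
  list(genotypes = geno, expression = sim$expression,
       annotation = sim$annotation, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d planted cis, %d planted trans, %d confounders, %d trait edges\n",
              nrow(x$planted_cis), nrow(x$planted_trans),
              ncol(x$confounder_loadings), nrow(x$trait_edges)))
  invisible(x)
}
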