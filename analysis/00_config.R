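# Shared study configuration for the analysis scripts. Sourced by every
# numbered driver so all stages regenerate the same synthetic cohorts
# deterministically instead of passing binary state between scripts.

library(wbeqtl)

STUDY_SEED <- 20140416L

# Discovery cohort: LD-blocked genotypes, three cis effects, one trans
# hotspot hitting six distant probes, two latent confounders.
study_config <- sim_config(
  n_individuals = 600L,
  n_snps = 80L,
  n_probes = 60L,
  maf_range = c(0.15, 0.45),
  ld_block_size = 8L,
  ld_decay = 0.9,
  cis_effects = list(
    list(snp = 6L,  probe = 1L, beta = 0.7),
    list(snp = 30L, probe = 2L, beta = -0.6),
    list(snp = 55L, probe = 3L, beta = 0.5)
  ),
  trans_hotspots = list(
    list(snp = 70L, probes = 10:15, betas = 0.6)
  ),
  n_confounders = 2L,
  confounder_sd = 2,
  noise_sd = 1,
  trait_models = list(
    # a trait downstream of a hotspot target probe (triangular structure)
    list(name = "trait_mpv", probe = 10L, beta = 0.8, noise_sd = 1),
    # a trait with no transcript intermediate
    list(name = "trait_null", probe = 40L, beta = 0, noise_sd = 1)
  ),
  seed = STUDY_SEED
)

REPLICATION_SEEDS <- c(coh_same_design = 101L, coh_diff_design = 202L)

# Analysis settings: PC counts match the planted confounder count; all
# other thresholds are the whole-blood defaults.
study_analysis_config <- analysis_config(
  n_pc_cis = 2L, n_pc_trans = 2L, n_pc_cis_replication = 2L
)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE)

build_discovery_cohort <- function() {
  geno <- simulate_genotypes(study_config)
  sim <- simulate_expression(geno, study_config)
  traits <- simulate_traits(sim$expression, geno, study_config)
  list(genotypes = geno, expression = sim$expression, truth = sim$truth,
       annotation = sim$annotation, traits = traits)
}

build_replication_cohorts <- function(truth) {
  lapply(REPLICATION_SEEDS, function(s) {
    rc <- simulate_replication_cohort(truth, study_config, new_seed = s)
    list(genotypes = rc$genotypes, expression = rc$expression)
  })
}
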