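#!/usr/bin/env Rscript
# Discovery-stage eQTL mapping on the synthetic cohort: QC, PC
# residualization, cis and trans scans, Bonferroni thresholds, lead-SNP
# selection and LD pruning of trans signals into loci.

source(file.path("analysis", "00_config.R"))

cohort <- build_discovery_cohort()
disc <- run_discovery(cohort$genotypes, cohort$expression,
                      cohort$annotation, study_analysis_config)

write_results(disc$cis$calls, file.path(results_dir, "cis_calls.tsv"),
              snp_map = disc$genotypes$map, annotation = cohort$annotation)
write_results(disc$trans$calls, file.path(results_dir, "trans_calls.tsv"),
              snp_map = disc$genotypes$map, annotation = cohort$annotation)
data.table::fwrite(disc$trans$loci, file.path(results_dir, "trans_loci.tsv"),
                   sep = "\t")
jsonlite::write_json(
  c(disc$summary,
    list(cis_tests = disc$cis$n_tests, cis_threshold = disc$cis$threshold,
         trans_tests = disc$trans$n_tests,
         trans_threshold = disc$trans$threshold)),
  file.path(results_dir, "discovery_summary.json"),
  auto_unbox = TRUE, digits = NA)

s <- disc$summary
cat(sprintf("cis scan: %d enumerated pairs, Bonferroni threshold %.3g\n",
            disc$cis$n_tests, disc$cis$threshold))
cat(sprintf("trans scan: %.0f combinations, Bonferroni threshold %.3g\n",
            disc$trans$n_tests, disc$trans$threshold))
cat(sprintf(
  "Called %d cis eQTLs and %d trans associations in %d loci (total %d)\n",
  s$n_cis, s$n_trans_pairs, s$n_trans_loci, s$total))

# recovery against the planted truth
truth <- cohort$truth
leads <- disc$cis$calls[disc$cis$calls$lead, ]
hit <- sum(truth$planted_cis$probe_id %in% leads$probe_id)
cat(sprintf("Planted cis effects with a significant lead: %d of %d\n",
            hit, nrow(truth$planted_cis)))
trans_hit <- sum(paste(truth$planted_trans$snp_id, truth$planted_trans$probe_id)
                 %in% paste(disc$trans$calls$snp_id, disc$trans$calls$probe_id))
cat(sprintf("Planted trans pairs called: %d of %d\n",
            trans_hit, nrow(truth$planted_trans)))
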