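#!/usr/bin/env Rscript
# Generate the synthetic discovery and replication cohorts and write them
# in the pipeline's interchange formats (VCF, dosage TSV, expression and
# trait TSV, probe annotation, truth ledger, YAML config).

source(file.path("analysis", "00_config.R"))

cohort <- build_discovery_cohort()

write_genotypes_vcf(cohort$genotypes, file.path(results_dir, "discovery.vcf"))
write_dosage_tsv(cohort$genotypes, file.path(results_dir, "discovery_dosage.tsv"))
write_matrix_tsv(cohort$expression, file.path(results_dir, "discovery_expression.tsv"))
write_matrix_tsv(cohort$traits, file.path(results_dir, "discovery_traits.tsv"))
write_probe_annotation(cohort$annotation, file.path(results_dir, "probe_annotation.tsv"))
write_analysis_config(study_analysis_config, file.path(results_dir, "analysis_config.yaml"))

truth_tab <- rbind(
  cbind(cohort$truth$planted_cis, class = "cis"),
  cbind(cohort$truth$planted_trans, class = "trans")
)
data.table::fwrite(truth_tab, file.path(results_dir, "truth_ledger.tsv"), sep = "\t")

reps <- build_replication_cohorts(cohort$truth)
for (nm in names(reps)) {
  write_dosage_tsv(reps[[nm]]$genotypes,
                   file.path(results_dir, paste0(nm, "_dosage.tsv")))
  write_matrix_tsv(reps[[nm]]$expression,
                   file.path(results_dir, paste0(nm, "_expression.tsv")))
}

cat(sprintf(
  "Simulated discovery cohort: %d individuals, %d SNPs, %d probes\n",
  nrow(cohort$genotypes$dosage), ncol(cohort$genotypes$dosage),
  ncol(cohort$expression)))
cat(sprintf("Planted truth: %d cis effects, %d trans (hotspot) effects\n",
            nrow(cohort$truth$planted_cis), nrow(cohort$truth$planted_trans)))
cat(sprintf("Replication cohorts: %s\n", paste(names(reps), collapse = ", ")))
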