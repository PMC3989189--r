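#!/usr/bin/env Rscript
# Downstream integration: master-regulator (trans-hotspot) detection,
# cross-study gene-overlap scoring against an independently simulated
# "other study", and triangular SNP-transcript-trait association around
# the planted hotspot.

source(file.path("analysis", "00_config.R"))

cohort <- build_discovery_cohort()
disc <- run_discovery(cohort$genotypes, cohort$expression,
                      cohort$annotation, study_analysis_config)

## master regulatory loci
ml <- detect_master_loci(disc$trans$calls, disc$trans$loci,
                         min_targets = study_analysis_config$master_min_targets,
                         multi_min = study_analysis_config$multi_target_min)
data.table::fwrite(ml$multi_target,
                   file.path(results_dir, "master_loci.tsv"), sep = "\t")
cat(sprintf("Multi-target trans loci (>= 2 genes): %d; master loci (>= %d genes): %d\n",
            nrow(ml$multi_target), study_analysis_config$master_min_targets,
            nrow(ml$master)))
if (nrow(ml$master) > 0) {
  cat(sprintf("  %s led by %s regulates %d genes in trans\n",
              ml$master$locus_id, ml$master$lead_snp, ml$master$target_count))
}

## cross-study overlap: an independent cohort drawn from the same truth
## stands in for a published study of the same tissue
other <- simulate_replication_cohort(cohort$truth, study_config, new_seed = 303L)
other_disc <- run_discovery(other$genotypes, other$expression,
                            other$annotation, study_analysis_config)
own_genes <- unique(na.omit(disc$cis$calls$gene[disc$cis$calls$lead]))
other_genes <- unique(na.omit(other_disc$cis$calls$gene[other_disc$cis$calls$lead]))
ov <- gene_overlap(own_genes, other_genes)
cat(sprintf("cis gene overlap with the comparison cohort: %d%% (%d of %d genes)\n",
            ov, length(intersect(own_genes, other_genes)), length(own_genes)))

## triangular relationships around the planted hotspot
traits <- simulate_traits(cohort$expression, cohort$genotypes, study_config)
hot_snp <- cohort$truth$planted_trans$snp_id[1]
tri_rows <- list()
for (pr in unique(cohort$truth$planted_trans$probe_id)) {
  for (tn in colnames(traits)) {
    tri <- triangular_test(disc$genotypes, cohort$expression, traits,
                           hot_snp, pr, tn)
    tri_rows[[length(tri_rows) + 1L]] <- data.frame(
      snp_id = hot_snp, probe_id = pr, trait = tn,
      p_snp_transcript = tri$edges$snp_transcript$p,
      p_snp_trait = tri$edges$snp_trait$p,
      p_transcript_trait = tri$edges$transcript_trait$p,
      verdict = tri$verdict)
  }
}
tri_tab <- do.call(rbind, tri_rows)
data.table::fwrite(tri_tab, file.path(results_dir, "triangles.tsv"), sep = "\t")
cat(sprintf("Triangular tests around %s: %d of %d SNP-transcript-trait triples supported\n",
            hot_snp, sum(tri_tab$verdict), nrow(tri_tab)))
print(tri_tab[tri_tab$verdict, c("probe_id", "trait")], row.names = FALSE)
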