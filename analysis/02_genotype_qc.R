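#!/usr/bin/env Rscript
# SNP quality control of the discovery cohort: MAF > 5%, call rate > 95%,
# HWE exact-test P > 1e-6 (all strict), reading the cohort back from the
# interchange files written by 01_simulate.R.

source(file.path("analysis", "00_config.R"))

geno <- read_genotypes(file.path(results_dir, "discovery_dosage.tsv"),
                       "dosage-tsv")
qc <- snp_qc(geno, study_analysis_config)
write_qc_report(qc$report, file.path(results_dir, "qc_report.tsv"))

print(qc$report)
cat(sprintf("Retained %d of %d SNPs (%.1f%%)\n", qc$report$n_pass,
            qc$report$n_input, 100 * qc$report$n_pass / qc$report$n_input))
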