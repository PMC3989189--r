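Package: wbeqtl
Title: Whole-Blood cis/trans eQTL Discovery and Replication Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for expression quantitative trait locus (eQTL) mapping in
    whole-blood cohorts: genotype quality control (minor allele frequency,
    call rate, Hardy-Weinberg exact test), principal-component
    residualization of expression confounders, mass additive linear
    regression scans of SNP-probe pairs, Bonferroni-based cis/trans calling
    with lead-SNP selection and LD-based locus clumping, replication in
    independent cohorts with proxy-SNP substitution and allelic-direction
    accounting, trans-hotspot (master regulator) detection, cross-study gene
    overlap scoring, and triangular SNP-transcript-trait association tests.
    Includes a synthetic cohort generator with planted cis/trans effects,
    LD block structure, latent expression confounders, and trait models, so
    the whole pipeline is testable end to end against a known truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
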