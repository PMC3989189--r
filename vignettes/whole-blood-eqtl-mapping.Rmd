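---
title: "Mapping cis and trans eQTLs in whole blood: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping cis and trans eQTLs in whole blood: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbeqtl)
```

## The problem

An expression quantitative trait locus (eQTL) is a genetic variant whose
genotype is statistically associated with the expression level of a
transcript. In population cohorts with array genotypes and whole-blood
expression arrays, the analysis is a mass simple-regression problem:
hundreds of thousands of SNPs against tens of thousands of probes, with
associations classified as *cis* (SNP within a fixed window of the
transcription unit) or *trans* (everything else), each class with its own
multiple-testing burden. `wbeqtl` implements this discovery-and-replication
pipeline together with a synthetic cohort generator, so every stage can be
exercised and validated against planted truth without access to any real
cohort.

## The statistical model

For a SNP with additive dosage $g_i \in \{0,1,2\}$ (count of the effect
allele) and a probe with expression $y_i$, the association model is
ordinary least squares on pairwise-complete cases:

$$y_i = \alpha + \beta g_i + \varepsilon_i, \qquad
t = \hat\beta / \mathrm{SE}(\hat\beta) \sim t_{n-2} \text{ under } H_0 .$$

`regress_single()` computes this in closed form; `assoc_scan()` runs it
blockwise over all requested SNP-probe pairs with results numerically
equal (to $10^{-8}$ relative, tested) to the per-pair computation.
Complete-case handling is pairwise, so the per-pair $n$ varies when calls
are missing — this mirrors the behaviour of the standard genetics
toolchain and is why result tables carry $n$ per row.

Significance is controlled by Bonferroni correction per class:
$p \le \alpha / m$ with $m$ the number of cis-enumerated pairs for the
cis scan and the total number of SNP-probe combinations for the trans
scan. At genome scale ($\alpha = 0.05$, 8,308,176 cis combinations,
$6.2\times10^5$ SNPs $\times$ $2.9\times10^4$ probes) these thresholds
are $6.0\times10^{-9}$ and $2.8\times10^{-12}$. Thresholds are kept at
full precision internally; 3-significant-figure rounding is display-only.

## Pipeline stages and their parameters

**SNP quality control** (`snp_qc`). Inclusion filters, all strict:
minor allele frequency $> 0.05$, call rate $> 0.95$, Hardy-Weinberg
exact-test $P > 10^{-6}$. The HWE test is the exact conditional test:
conditional on the allele counts, the p-value sums the probabilities of
all heterozygote counts no more probable than the observed one. It is
computed in log space and agrees with a direct-factorial enumeration
oracle on the exhaustive grid of totals up to 50 (tested). The
chi-square approximation is deliberately not offered: the exact test is
the QC standard and remains well defined at low counts. All SNPs are
treated autosomally; no sex-chromosome special-casing is applied.

**Expression confounder removal** (`compute_pcs`, `residualize`,
`pc_sweep`). Latent structure (batch, cell-type composition, technical
variation) is removed by residualizing each probe on the top $k$
principal components of the probe-standardized expression matrix.
Components are left singular vectors with a fixed sign convention (the
largest-magnitude entry of each component is positive) so the
decomposition is deterministic. Residualization is an orthogonal
projection: residuals are exactly orthogonal to the basis, per-probe
variance cannot increase, and the operation is idempotent (all tested).
$k$ is a configuration value, not automatically selected: `pc_sweep`
emits the evidence table (mean standard error, mean $|\beta|$,
significant-call counts over a pair subset for $k = 0$ and a grid), and
the analyst chooses. Defaults are 55 (cis) and 25 (trans) for discovery
and 50 (cis) at replication, the convention for whole-blood array
cohorts of $\sim$900 samples; the bundled synthetic study uses $k = 2$,
matching its planted confounder count.

**Calling** (`call_cis`, `prune_trans`). A pair is cis when the SNP lies
within 500 kb of the transcription unit, **boundaries inclusive**
($\mathrm{tx\_start} - 500\,\mathrm{kb} \le \mathrm{pos} \le
\mathrm{tx\_end} + 500\,\mathrm{kb}$); the off-by-one choice at exactly
500 kb cannot be resolved against published counts, so the inclusive
convention is fixed here and documented. Per probe, the smallest-p SNP in
the window is flagged lead; ties break by smaller position, then SNP id.
All significant pairs are retained (so genes supported by several probes
remain visible); the lead flag defines the one reported cis-eQTL per
probe. Trans associations are reduced in two steps: (1) SNPs in high LD
($r^2 > 0.5$) with any significant cis SNP are dropped; (2) the rest are
greedily clumped by ascending best p-value — a SNP joins the existing
locus whose lead it exceeds $r^2 = 0.5$ with (highest $r^2$ wins),
otherwise it founds a new locus. "High LD" is interpreted as squared
Pearson correlation of dosages ($r^2$, the pruning convention), not
$|r|$, and is configurable. The resulting invariants — no retained trans
SNP tied to a cis signal, members tied to their lead, leads mutually
unlinked — are asserted in the test suite on every run.

**Replication** (`replication_thresholds`, `find_proxy`,
`replicate_calls`). Replication thresholds divide $\alpha$ by the number
of *discovered associations* per class (not loci). When a discovery SNP
is absent from a replication cohort, the best proxy within 500 kb at
$r^2 \ge 0.8$ (computed in the discovery panel, which contains both
SNPs) substitutes; absence of a proxy is recorded, not an error. Before
each replication regression, cohort expression PCs associated with the
SNP of interest (nominal $p < 0.05$ per component) are excluded from the
residualization so true genetic signal is not regressed away. Effect
alleles are harmonized before sign comparison: a ref/alt swap flips the
slope, and proxies are oriented by the sign of their dosage correlation
with the discovery SNP in the reference panel. A cis call replicates as
a SNP-probe pair; a trans locus replicates when any member association
does. All percentages are recomputed from raw counts with
half-away-from-zero integer rounding (91.38 → 91, 91.55 → 92), never
cached.

**Downstream integration** (`detect_master_loci`, `gene_overlap`,
`triangular_test`). A trans locus whose confirmed calls cover five or
more distinct target genes (probe id standing in where no gene is
assigned) is a master regulatory locus; loci with two or more targets go
to the multi-target report. Cross-study overlap is
$\mathrm{round}(100 \cdot \text{shared genes} / \text{own genes})$, with
both numerator and denominator overridable because published
comparisons often restrict "shared" to genes annotatable on both
platforms. The triangular test reports the three marginal OLS edges
SNP→transcript, SNP→trait and transcript→trait, with a positive verdict
when all reach a nominal $\alpha = 0.05$; no mediation decomposition or
multiplicity correction is applied to these follow-ups, which are
hypothesis-generating by design.

## The synthetic cohort generator

`sim_config()` + `simulate_genotypes()` / `simulate_expression()` /
`simulate_traits()` / `simulate_replication_cohort()` generate cohorts
with the structure the pipeline assumes:

- **Genotypes.** Per-SNP MAF uniform on a configurable range (default
  0.1–0.5, satisfying the MAF > 5% filter). The two haplotypes of an
  individual are independent, so Hardy-Weinberg proportions hold exactly
  by construction; within a haplotype, alleles follow a Gaussian copula
  whose latent process is AR(1) with coefficient `ld_decay` inside each
  LD block, giving geometrically decaying dosage correlation. Note the
  achievable dosage $r^2$ between neighbours is capped below the latent
  correlation when their MAFs differ; fixtures that need $r^2 > 0.8$ use
  narrow MAF ranges or explicit near-copies.
- **Expression.** Each probe is latent-factor signal (loadings $\times$
  scores, `n_confounders` factors) plus Gaussian noise, standardized to
  mean 0, SD 1 — a stand-in for upstream array normalization, which is
  out of scope and unspecified for real cohorts — after which the planted
  additive effects $\beta \cdot (g - \bar g)$ are added. Planted betas
  are therefore in SD units of the pre-genetic expression signal.
- **Determinism.** One seed drives everything; each stage derives its
  stream as seed + fixed offset (genotypes 0, expression 1, traits 2),
  and the draw order within a stage is fixed (MAFs, then haplotype one,
  then haplotype two). Identical configuration and seed give
  bit-identical output, tested.
- **Truth ledger.** Every nonzero planted effect appears exactly once in
  `sim_truth`, which also carries the confounder loadings and trait
  edges; replication cohorts are drawn from the same ledger with a new
  seed, so effect signs carry over while realizations are independent.

The generator deliberately omits population structure and admixture,
imputation uncertainty (calls are hard 0/1/2), and probe
cross-hybridization.

## What desk-scale validation does and does not show

The validation suite runs at sizes a laptop handles in minutes; the
vignette states them as the package's own choices: family-wise error is
measured on 200 pure-null cohorts of 200 samples $\times$ 2,000 SNPs
$\times$ 200 probes; cis lead recovery on 20 cohorts of 500 samples with
planted $\beta = 0.6$; hotspot recovery on 20 cohorts of 900 samples
with a 13-target hotspot at $\beta = 0.5$; direction consistency on 50
paired 900-sample cohorts with $\beta = 0.8$.

One desk-scale artifact deserves explicit mention. Removing *estimated*
expression PCs is an orthogonal projection onto data-derived directions;
when a trans hotspot spans a non-trivial fraction of the phenome (13 of
80 probes in a small simulation), the hotspot itself loads on the top
components, and projecting it out injects a small, sign-mixed copy of
the dosage signal into unrelated probes — spurious trans associations
that can clear a desk-scale Bonferroni threshold. In a genome-scale
cohort the same hotspot is 13 of ~29,000 probes and the leakage is
negligible. The recovery, family-wise-error and direction-consistency
validations therefore run on confounder-free cohorts with zero
components removed, isolating the machinery they are meant to test;
confounder removal itself is validated separately (planted-factor
removal to numerical zero, and a power comparison showing association
power at the matched $k$ strictly exceeds the uncorrected scan).
Passing these tests demonstrates the correctness of the calling,
pruning and accounting machinery under the generator's assumptions —
not robustness to real-data pathologies such as non-Gaussian expression,
batch-confounded genotypes, or cell-composition shifts.

Relatedly, the greedy clumping of an extended LD block can split one
planted hotspot into several reported loci when non-adjacent block
members fall below the $r^2 = 0.5$ tie to the current lead; the reported
locus count is a convention-dependent summary, which is why the
underlying SNP-probe associations are always retained alongside.

## Numerical choices

- p-values are floored at $10^{-300}$; floored and perfect-fit results
  carry a flag rather than silently reporting 0.
- Degenerate regressions (constant dosage, $n < 3$) are flagged and
  excluded downstream, never errors mid-scan.
- Thresholding uses $p \le$ threshold at full precision.
- Percentages round half away from zero; R's default round-half-even
  would disagree with conventional reporting at .5 boundaries.
- Positions are 0-based half-open internally (BED-native); VCF positions
  convert on read/write. Dosage counts the ALT allele, recorded as the
  effect allele in every result row, which makes allele harmonization at
  replication time mechanical.
- PC sign convention and deterministic orderings (results by ascending p
  then snp_id; locus ids by founding order) make every output
  reproducible byte for byte under a fixed seed.

## Known limitations

- Bonferroni only; no FDR alternatives, no conditional/stepwise
  secondary-signal analysis within a window.
- No mixed models or kinship correction; samples are assumed unrelated.
- The clumping algorithm is a stated convention (greedy, p-ordered,
  lead-anchored $r^2$); published locus counts from other pipelines may
  differ for identical data.
- Cross-study overlap and phenotype joins operate on user-supplied
  tables; no external catalog is bundled.
- The triangular test reports marginal edges only; a significant
  triangle is consistent with, but not evidence of, mediation.
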