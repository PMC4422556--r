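---
title: "Methods: genetically inferred causal modules and network key drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically inferred causal modules and network key drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`netdriver` chains five statistical procedures — covariate
residualization, single-gene trait association, weighted coexpression
module detection, SNP-set enrichment against GWAS summary statistics, and
network key-driver analysis — into one workflow for deciding which
trait-correlated parts of a transcriptome are *upstream* of the trait, and
which genes regulate them. This vignette records the models, the
parameters that matter, the numerical conventions, and the choices made
where the design was genuinely open. Nothing here reports an empirical
result that the test suite and `scripts/acceptance.R` do not themselves
compute.

## Residualization and the cell-type scan

Expression is adjusted by per-gene ordinary least squares on an explicit
covariate design (intercept always present; categorical covariates
expanded to indicators; collinear columns dropped after a QR rank check).
Residuals are exactly orthogonal to the design, and residualizing twice is
a no-op; both are tested against the explicit projection matrix
`I − X(XᵀX)⁻¹Xᵀ`.

Large family studies adjust such models for relatedness with kinship
random effects. Pedigrees are out of scope here: the package substitutes
fixed-effects OLS, and its simulated samples are unrelated, so the
substitution is exact for all shipped data. With related samples the
p-values downstream would be anti-conservative; that is a documented
limitation, not a target of this implementation.

Whole-blood expression tracks cell composition strongly, so the workflow
quantifies it (per-gene F-test of the joint cell-proportion regression,
Bonferroni over genes) and can run entirely with or without cell
adjustment (`adjust_cell_types` in `run_pipeline()`); the adjusted track
is primary.

## Single-gene associations and the signature

Each gene × trait pair gets a simple linear regression of trait on
residual expression — numerically the Pearson correlation with a two-sided
t test. The binary hypertension flag (SBP ≥ 140 mm Hg or DBP ≥ 90 mm Hg)
goes through the same linear score test so that all three traits share one
framework; logistic regression is available behind a flag and agrees in
ordering. Significance is Bonferroni at family α = 0.05 over genes, per
trait; the signature set is the union across traits, reported with
per-trait counts and direction tallies.

## Coexpression modules

The network is unsigned: `a_ij = |r_ij|^β`. β is selected as the smallest
power whose connectivity histogram (10 equal-width bins, empty bins
dropped, log10 on both axes) fits a line with R² > 0.8; if none passes,
the best-fitting power is used with a warning. The selection statistic is
by default a 3-point running mean of the R² curve across the scanned
ladder: at a few hundred genes the per-power binned R² is noisy, and an
isolated chance pass at β = 2–3 selects an over-dense network whose
modules the dendrogram cut cannot separate (measured as recovery ARI
0.1–0.5 in the affected runs); the raw per-power rule is available via
`smooth = FALSE`. `pick_soft_power()` scans
1–20 by default; `run_pipeline()` scans 1–10, because on networks of a few
hundred genes powers above ~10 drive the topological overlap toward zero
and the fixed-height dendrogram cut then dissolves genuine modules
(measured as a collapse of recovery ARI from 1.0 to 0 between β = 10 and
β = 14 on the simulated conditions below). β is unitless; 6–8 is typical
for unsigned networks at these sizes.

Genes are clustered by average-linkage hierarchical clustering on
`1 − TOM`, where TOM is the unsigned topological overlap with the
min-connectivity denominator (formula in the README; verified against a
triple-loop oracle at 1e-10). The dynamic cut is deliberately simple: a
static cut at `cut_height_frac = 0.99` of the maximum merge height, every
branch of at least `min_size = 30` genes becoming a module, followed by
one re-examination per branch — the sub-dendrogram is re-cut at its
largest internal merge-height gap, and the split is kept only if all
pieces still reach `min_size`. This is not a line-for-line port of the
published hybrid tree-cut algorithm; module recovery, not algorithmic
identity, is the contract, and the recovery benchmark (ARI ≥ 0.8 at
within-module correlation 0.6, n = 200, 10 seeds) is part of the test
suite. Module labels are colors by decreasing size; `grey` collects
unassigned genes. No eigengene-merging step is applied (flag available,
default off).

Module eigengenes are the first right singular vectors of the
gene-standardized member submatrices, sign-oriented so the mean member
correlation is non-negative; variance explained is the first squared
singular value over the total. Eigengene–trait association uses Pearson
correlation with raw (unadjusted) trait values, two-sided t p-values, BH
FDR across module × trait pairs, and reporting tiers p < 0.05, FDR < 0.2,
FDR < 0.05; a module's headline association is its minimum p over traits.

## SNP-set enrichment analysis

For a gene set, take the union of its members' eSNPs (cis and trans,
upstream-filtered at eQTL FDR < 0.1), then LD-prune: SNPs are ranked by
their best eQTL p (ties by SNP id) and greedily retained, discarding
remaining SNPs with r² ≥ 0.8 to a kept SNP. Ranking by eQTL rather than
GWAS p keeps the selection blind to the outcome being tested; the paper
trail for the kept-SNP rule is silent, and this choice makes the null
unbiased. The same pruning produces the background from all eSNPs. Two
one-sided tests compare the set's GWAS p-values to the background:

* **KS** — exact conditional one-sided two-sample Kolmogorov–Smirnov test
  of "set p-values stochastically smaller". The exact (permutation) null
  of the one-sided statistic is used because the classical asymptotic tail
  `exp(−2D²mn/(m+n))` is visibly conservative in the mid-range at the
  sample sizes this package operates at (~75 vs ~800 after pruning), which
  would distort calibration checks.
* **Fisher** — dichotomize all eSNPs at GWAS p < 0.05 and test the 2 × 2
  set × significance table one-sided. The p-value is computed as the upper
  hypergeometric tail, which is identical to the one-sided Fisher exact
  test and ~10³ times faster across the permutation loop; equality with
  `stats::fisher.test` is asserted in the tests.

The tested set's SNPs are *excluded* from the background. At the scale the
package ships (600 genes, ~800 pruned background SNPs) a module's eSNPs
are 10–25% of the background; leaving them nested makes the two samples
dependent and the null strongly conservative, and the package's own
calibration requirement (null p_KS within KS-distance 0.05 of uniform over
1,000 simulated sets) is then unattainable. When sets are a negligible
fraction of the background — the regime of a full blood eQTL panel — the
two conventions coincide.

Permutation calibration draws 1,000 gene sets of matching size from the
pool of genes with at least one eSNP, runs the identical
map → prune → test chain, and reports `#{perm p < observed p}/1000`
(strict inequality; a zero count is printed `"<0.001"`). Bonferroni
correction is across the number of gene sets tested (seven in the default
workflow: one signature + six modules); a set is *genetically inferred
causal* when both corrected analytic tests pass at 0.05 for at least one
trait.

## Key-driver analysis

A candidate's neighborhood is all nodes within graph distance 3 (direction
ignored on directed networks; downstream-only expansion behind a flag),
excluding the candidate; the 2 × 2 universe is all other network nodes, so
a candidate never counts itself. Candidates are the nodes of the gene
set's 3rd-layer expanding network (union of members' ≤3-step
neighborhoods, members included), and the Bonferroni correction count is
that pool's size — the set-specific reading of "corrected for the number
of genes in the 3rd-layer expanding network"; correcting by all network
nodes is available via `correct_all_nodes`. Set members may themselves be
key drivers; no exclusion rule is applied. Ranking tiers: KDs whose own
eSNPs reach GWAS p < 1e-5 (sorted by that p), then transcriptome-wide
Bonferroni-significant KDs (by association p), then KDs significant in ≥2
networks (by KD p), then the rest. Replication in a second network
requires presence plus Bonferroni significance there for the same set.

## Subnetworks and enrichment

Genetic subnetworks are stars from a SNP to all its eSNP target genes,
edges labeled cis/trans, nodes labeled by candidate-set membership.
Interaction subnetworks are induced subgraphs on a key driver plus its
3-layer neighborhood. All set enrichments share one object: overlap k,
query n, reference K, universe N, `fold = (k/n)/(K/N)`, upper-tail
hypergeometric `P(X ≥ k)`. The universe is always an explicit argument —
the correct background (e.g. all genes with any literature annotation)
changes the answer, so the package refuses to infer it silently. Mouse
knockout DE calls (q < 0.05, direction ignored) map to human symbols
through a 1:1 ortholog table before enrichment. In `run_pipeline()` the
knockout overlap is evaluated on the knockout *target's* subnetwork — the
targeted gene is experimental metadata, known regardless of where the KD
ranking puts it — while the summary separately records whether the target
was detected as a KD and whether the top-ranked KD is a planted hub.

## The synthetic study conditions

`sim_config()` fixes the conditions every recovery and calibration test
runs under; they are study design, not tuning knobs.

* **Expression**: 200 unrelated samples, 600 genes; six modules of sizes
  50, 45, 40, 35, 30, 30 with within-module correlation target 0.6 (gene
  = `sqrt(0.6)` × module factor + noise); 370 pure-noise genes. 40% of
  genes carry a cell-composition component of standard deviation 0.45 (the
  component is standardized per gene because the three compositional cell
  proportions span only two free dimensions; without standardization a
  random direction can silently lose its variance). Units are arbitrary
  log-expression scale.
* **Traits**: SBP = Σ r_m × factor_m + covariate effects (age 0.25, sex
  0.10, BMI 0.20 on the standardized scale) + noise, mapped to
  120 ± 15 mm Hg; planted factor–trait correlations r_m = 0.1 for five
  modules and 0 for one — the weak-signal regime blood transcriptomics
  operates in, where module-level statistics, not single genes, carry the
  association (single-gene signatures are therefore small and unstable
  across seeds, as they are in practice). DBP shares the SBP core at
  ρ = 0.6 (80 ± 10 mm Hg); hypertension is the threshold rule.
* **Genetics**: 3,000 SNPs in 3-SNP LD blocks (block members are copies of
  a seed dosage vector with 3% per-sample redraw noise, giving within-block
  r² ≳ 0.8; MAF uniform on 0.1–0.4; 400-sample reference panel). Each gene
  gets 2 eSNPs (one cis, one trans; eQTL p 10^−U(3,8), FDR < 0.09). eSNPs
  of the four causal modules draw GWAS p from a 1-df non-central χ² with
  non-centrality 30 (SBP) and 21 (DBP); all other SNPs are uniform. The
  3,000/3 scale keeps the pruned background near 800 SNPs, large enough
  for the exact KS p to be calibrated.
* **Network**: 2,000 nodes; one preferential-attachment component per
  planted key driver (plus a background component, sparse bridges), each
  hub the best-branched high-degree node of its component. A hub's planted
  module genes sit on its 3rd shell, at most one per branch, at rate 0.9
  of the available slots; the hub itself carries a non-module measured
  gene, and module genes that found no planted slot stay out of the
  network (as interaction databases cover only part of any expression
  panel). This outer-shell, one-per-branch construction is what gives
  key-driver recovery a well-defined positive set: neighborhood enrichment
  is a *regional* property, and filling the whole ≤3-step ball would make
  every node near a hub significant, leaving no meaningful notion of
  "the" planted driver. The literal fill-the-ball construction remains
  available (`stuff_all_layers = TRUE`), where at rate 1 the hub's
  neighborhood is contained in the causal set by construction. Degree
  sequences remain power-law (binned log-log R² ≥ 0.8 at 2,000 nodes).
* **Knockout**: the first hub is the target; measured genes in its 3-layer
  neighborhood are called DE with probability 0.4, others 0.15; q-values
  are drawn consistently with the calls.

One global seed expands into per-stage sub-streams (`stage_seed()`), so
any stage can be regenerated alone and identical seed + config give
byte-identical files.

What the generator does *not* emulate: familial relatedness, count-scale
expression noise (the factor model is Gaussian), realistic population LD
(blocks are exchangeable copies, and GWAS p-values of linked SNPs are
drawn independently), many-to-many orthology, and networks whose
enrichment structure is diffuse rather than hub-centered. Passing recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to those real-data complications.

## Numerical conventions and calibration protocol

Gene symbols are uppercased once at load and matched case-sensitively
afterwards. Positions are 1-based. p-values are clamped to (0, 1];
permutation p uses strict inequality. LD pruning is deterministic (ties in
eQTL p broken lexicographically), and its output is independent of input
order. Degenerate inputs fail loudly with classed errors (zero-variance
genes, constant traits, empty universes) or are flagged (constant dosage
columns get r² 0 with a warning; sets without eSNPs get an explicit
status).

Null calibration of SSEA estimates the null distribution of the analytic
KS p over 1,000 simulated gene sets, each evaluated against its own null
GWAS draw on a shared eSNP/LD structure. With a single shared GWAS
realization the 1,000 values are positively dependent (sets overlap in
SNPs) and their empirical distance from uniform fluctuates well above the
independent-sampling band even when the marginal distribution is exact;
independent draws make the Monte Carlo estimate well-defined. The
familywise null checks (no causal calls among seven null sets; no
significant key drivers under random labels) run over 30 fixed seeds:
the underlying Bonferroni procedures have a familywise error near 3–5% by
construction, so a ≥95%-of-seeds assertion needs enough seeds for the
proportion to be stable, and fixed seeds make the check deterministic.

## Known limitations

Fixed-effects residualization (no kinship); no block-wise computation for
very large gene sets (the full TOM is materialized, so ~20k genes needs
~3 GB); no consensus/multi-tissue modules; no GO-DAG propagation (flat
term sets); no Bayesian-network structure learning (directed networks are
consumed as inputs); the permutation scheme matches gene-set size only,
not gene properties such as eSNP count; and the hypergeometric framework
tests enrichment, never depletion.
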