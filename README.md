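# netdriver

Genetically inferred causal gene modules and network key drivers for a
quantitative trait.

Genome-wide association studies identify loci for complex traits such as
blood pressure, but a trait-correlated transcript can be a cause of trait
variation, a consequence of it, or a bystander. `netdriver` implements an
integrative workflow that separates these cases and then pinpoints the
regulators of the causal signal:

1. **Preprocess** — residualize a genes × samples expression matrix on
   covariates (age, sex, BMI, cohort, measured blood cell-type
   proportions) by per-gene OLS, and quantify how much of the
   transcriptome tracks cell composition.
2. **Single-gene associations** — Pearson correlation of each gene with
   SBP, DBP and hypertension status; the Bonferroni-significant union is
   the trait *signature gene set*.
3. **Coexpression modules** — a weighted gene coexpression network:
   unsigned adjacency `a_ij = |cor(x_i, x_j)|^β` with β chosen as the
   smallest power whose connectivity distribution fits a scale-free law
   (R² of log10 p(k) on log10 k > 0.8); genes clustered by average linkage
   on the topological overlap dissimilarity `1 − w_ij`, where

   ```
   w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij),
   l_ij = Σ_{u≠i,j} a_iu a_uj,   k_i = Σ_{u≠i} a_iu,
   ```

   with a dynamic cut of the dendrogram into modules; module eigengenes
   (first principal component of the standardized member submatrix) are
   correlated with the traits (BH FDR across module × trait pairs).
4. **SNP-set enrichment (SSEA)** — map each gene set (signature + modules)
   to its eSNPs, LD-prune at r² ≥ 0.8 (keeping the best-eQTL SNP per
   clump), and ask whether the set's GWAS p-values are stochastically
   smaller than the pruned background of all eSNPs: a one-sided exact
   two-sample Kolmogorov–Smirnov test and a one-sided Fisher test on the
   p < 0.05 dichotomy, calibrated by 1,000 size-matched gene-set
   permutations and Bonferroni-corrected across sets. A set passing both
   corrected tests is *genetically inferred causal*.
5. **Key drivers (KD)** — on a molecular interaction network, test every
   node of a causal set's 3rd-layer expanding network for enrichment of
   set members in its 1st–3rd-layer neighborhood (one-sided Fisher,
   Bonferroni by candidate-pool size), rank KDs by eSNP GWAS evidence,
   transcriptome-wide association, and multi-network support, and test
   replication in an independent network.
6. **Subnetworks and validation** — genetic (SNP-centered star) and
   interaction (KD-centered) subnetworks, with hypergeometric enrichment
   (`fold = (k/n)/(K/N)`, `p = P(X ≥ k)`) against literature gene lists,
   flat annotation terms (Bonferroni over terms), and a cross-species
   knockout differential-expression signature mapped through 1:1
   orthologs.

Every input the pipeline consumes can also be *simulated* with planted
ground truth (`sim_config()`, `simulate_all()`): factor-model expression
with planted modules, weak module–trait coupling, block-LD genotypes,
eSNPs with inflated GWAS association for the causal modules, a
preferential-attachment interaction network with one planted key-driver
hub per causal module, and a knockout DE list concentrated in one hub's
neighborhood. Each stage therefore has a parameter-recovery test with no
external downloads.

## Worked example

The numbered drivers under `analysis/` run the whole study on simulated
data (seed 1), writing every stage table under `results/run/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Selected output of that run:

```
Simulated 600 genes x 200 samples; 3000 SNPs; network of 2000 nodes.
Planted causal modules: M1, M2, M3, M4. Planted key drivers: GENE0411, GENE0402, GENE0329, GENE0536.
39% of genes associate with cell proportions at Bonferroni p < 0.05.
Signature: 14 genes (per-trait: SBP=14); 14 positive, 0 negative.
Soft power 8 (fit R2 0.83).
6 modules: turquoise=50, blue=45, brown=40, yellow=35, green=30, red=30.
7 gene sets tested; genetically inferred causal: signature, blue, brown, turquoise, yellow.
Top key driver: GENE0411 (tier OTHER).
Knockout DE overlap: 20 of 47 subnetwork genes (fold 2.53, p = 1.2e-05).
Causal modules map to planted M1, M2, M3, M4 (truth: M1, M2, M3, M4).
Top-ranked key driver GENE0411 is a planted hub.
```

Reading: the six detected modules are the six planted ones (sizes 50–30);
the four modules called causal by SSEA map exactly onto the four planted
causal modules (the 14-gene signature, a trait-correlated slice of module
M1, is also flagged — its genes are genuinely causal here); the top-ranked
key driver is the planted hub of M1; and the simulated knockout of that
hub yields a DE signature 2.5-fold enriched in the hub's subnetwork.

The same end-to-end run is available as one call:

```r
library(netdriver)
summary <- run_pipeline(sim_config(seed = 1), "results/run")
```

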