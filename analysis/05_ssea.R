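#!/usr/bin/env Rscript
# SNP-set enrichment: do the eSNPs of each gene set carry more GWAS signal
# than the LD-pruned background of all eSNPs? Both KS and Fisher tests,
# 1,000 size-matched permutations, Bonferroni over the tested sets; a set
# passing both corrected tests for a trait is genetically inferred causal.
suppressMessages(library(netdriver))

run <- file.path("results", "run")
seed <- as.integer(Sys.getenv("ND_SEED", "1"))
sets <- read_gmt(file.path(run, "gene_sets.gmt"))
esnp <- read_esnp(file.path(run, "inputs", "esnp.tsv"))
gwas <- read_gwas(file.path(run, "inputs", "gwas.tsv"))
dos <- utils::read.delim(file.path(run, "inputs", "dosages.tsv"),
                         check.names = FALSE)
ld <- compute_ld(as.matrix(dos[, -1]))

res <- ssea_run(sets, esnp, gwas, ld, n_perm = 1000,
                seed = stage_seed(seed, "ssea"))
write_tsv(res, file.path(run, "ssea.tsv"))
called <- unique(res$gene_set[res$causal_call])
cat(sprintf("%d gene sets tested; genetically inferred causal: %s.\n",
            length(sets), paste(called, collapse = ", ")))
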