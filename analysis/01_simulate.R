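#!/usr/bin/env Rscript
# Generate the synthetic study inputs: expression with six planted
# coexpression modules, blood-pressure phenotypes driven weakly by four of
# them, eSNPs whose causal-module SNPs carry GWAS signal, block-LD dosages,
# an interaction network with one planted key-driver hub per causal module,
# and a knockout DE signature around the first hub.
suppressMessages(library(netdriver))

seed <- as.integer(Sys.getenv("ND_SEED", "1"))
outdir <- file.path("results", "run", "inputs")
cfg <- sim_config(seed = seed)
sim <- simulate_all(cfg, outdir)

cat(sprintf("Simulated %d genes x %d samples; %d SNPs; network of %d nodes.\n",
            nrow(sim$expr), ncol(sim$expr), nrow(sim$gwas),
            igraph::vcount(sim$network)))
cat(sprintf("Planted causal modules: %s. Planted key drivers: %s.\n",
            paste(sim$truth$true_causal_modules, collapse = ", "),
            paste(sim$truth$true_kds, collapse = ", ")))
cat("Inputs written under", outdir, "\n")
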