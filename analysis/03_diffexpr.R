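#!/usr/bin/env Rscript
# Single-gene association of residual expression with SBP, DBP and the
# hypertension flag; the Bonferroni-significant union is the trait
# signature gene set.
suppressMessages(library(netdriver))

run <- file.path("results", "run")
resid <- read_expression(file.path(run, "residuals.tsv"))
phen <- read_phenotypes(file.path(run, "inputs", "phenotypes.tsv"))

assoc <- associate_traits(resid, phen)
write_tsv(assoc, file.path(run, "trait_associations.tsv"))
sig <- signature_set(assoc)
cat(sprintf("Signature: %d genes (per-trait: %s); %d positive, %d negative.\n",
            length(sig$genes),
            paste(names(sig$per_trait_counts), sig$per_trait_counts,
                  sep = "=", collapse = ", "),
            sig$n_positive, sig$n_negative))
if (length(sig$genes))
  write_gmt(list(signature = sig$genes), file.path(run, "signature.gmt"))
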