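#!/usr/bin/env Rscript
# Subnetwork validation: build the knockout target's interaction subnetwork
# and a genetic subnetwork around one of its eSNPs, then test the
# interaction subnetwork against the cross-species knockout DE signature.
suppressMessages(library(netdriver))

run <- file.path("results", "run")
net <- read_network(file.path(run, "inputs", "network.tsv"))
esnp <- read_esnp(file.path(run, "inputs", "esnp.tsv"))
mouse <- read_mouse_de(file.path(run, "inputs", "mouse_de.tsv"))
orth <- read_orthologs(file.path(run, "inputs", "orthologs.tsv"))
expr <- read_expression(file.path(run, "inputs", "expression.tsv"))
truth <- jsonlite::read_json(file.path(run, "inputs", "truth.json"))
sets <- read_gmt(file.path(run, "gene_sets.gmt"))

target <- truth$mouse_target_kd
sub <- interaction_subnetwork(net, target, depth = 3)
cat(sprintf("%s interaction subnetwork: %d genes.\n", target, length(sub$genes)))
write_tsv(data.frame(gene = sub$genes), file.path(run, "subnetwork_genes.tsv"))

snps <- esnp$snp_id[esnp$gene_id == target]
if (length(snps)) {
  gs <- genetic_subnetwork(snps[1], esnp, sets["signature"])
  cat(sprintf("Genetic subnetwork of %s: %d gene(s) (%d cis, %d trans).\n",
              snps[1], nrow(gs$nodes), sum(gs$nodes$kind == "cis"),
              sum(gs$nodes$kind == "trans")))
  write_tsv(gs$edges, file.path(run, "genetic_subnetwork.tsv"))
}

mo <- mouse_overlap(sub$genes, mouse, orth, universe = rownames(expr))
cat(sprintf("Knockout DE overlap: %d of %d subnetwork genes (fold %.2f, p = %.2g).\n",
            mo$k, mo$n, mo$fold, mo$p))
write_tsv(as.data.frame(mo[c("k", "n", "K", "N", "fold", "p")]),
          file.path(run, "mouse_overlap.tsv"))
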