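#!/usr/bin/env Rscript
# Weighted coexpression network: soft power by scale-free fit, topological
# overlap, dynamic dendrogram cut into modules, eigengenes, module-trait
# association, and enrichment of the signature in each module.
suppressMessages(library(netdriver))

run <- file.path("results", "run")
resid <- read_expression(file.path(run, "residuals.tsv"))
phen <- read_phenotypes(file.path(run, "inputs", "phenotypes.tsv"))

fit <- pick_soft_power(resid, powers = 1:10)
write_tsv(fit$fits, file.path(run, "soft_power_fit.tsv"))
cat(sprintf("Soft power %d (fit R2 %.2f).\n", fit$power,
            fit$fits$r2[fit$fits$power == fit$power]))

net <- build_network(resid, fit$power)
part <- detect_modules(net)
write_tsv(data.frame(gene_id = names(part$labels), module = part$labels),
          file.path(run, "modules.tsv"))
cat(sprintf("%d modules: %s.\n", length(part$sizes),
            paste(names(part$sizes), part$sizes, sep = "=", collapse = ", ")))

eig <- module_eigengenes(resid, part$labels)
mt <- module_trait(eig$eigengenes, phen)
write_tsv(mt, file.path(run, "module_trait.tsv"))
cat(sprintf("Modules at p<0.05 for a BP trait: %s.\n",
            paste(unique(mt$module[mt$sig_p05]), collapse = ", ")))

sets <- split(names(part$labels), part$labels)
sets <- sets[setdiff(names(sets), "grey")]
sigf <- file.path(run, "signature.gmt")
if (file.exists(sigf)) {
  sig <- read_gmt(sigf)$signature
  mse <- module_signature_enrichment(part$labels, sig)
  write_tsv(mse, file.path(run, "module_signature.tsv"))
  sets <- c(list(signature = sig), sets)
}
write_gmt(sets, file.path(run, "gene_sets.gmt"))
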