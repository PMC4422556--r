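#!/usr/bin/env Rscript
# Render the markdown report for the run directory, plus a one-shot
# comparison of the detected causal modules and key drivers against the
# generator's planted truth.
suppressMessages(library(netdriver))

run <- file.path("results", "run")
path <- report(run)
cat("Report written to", path, "\n")

truth <- jsonlite::read_json(file.path(run, "inputs", "truth.json"))
modules <- utils::read.delim(file.path(run, "modules.tsv"), stringsAsFactors = FALSE)
labels <- setNames(modules$module, modules$gene_id)
reference <- setNames(unlist(truth$true_partition), names(truth$true_partition))
mm <- match_modules(labels, reference)
write_tsv(mm, file.path(run, "module_truth_match.tsv"))

ssea <- utils::read.delim(file.path(run, "ssea.tsv"), stringsAsFactors = FALSE)
causal <- setdiff(unique(ssea$gene_set[ssea$causal_call]), "signature")
matched <- sort(unique(mm$matched[mm$detected %in% causal]))
cat(sprintf("Causal modules map to planted %s (truth: %s).\n",
            paste(matched, collapse = ", "),
            paste(sort(unlist(truth$true_causal_modules)), collapse = ", ")))
kd <- utils::read.delim(file.path(run, "key_drivers.tsv"), stringsAsFactors = FALSE)
cat(sprintf("Top-ranked key driver %s is %s planted hub.\n", kd$gene[1],
            if (kd$gene[1] %in% unlist(truth$true_kds)) "a" else "not a"))
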