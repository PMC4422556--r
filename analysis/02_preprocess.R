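#!/usr/bin/env Rscript
# Residualize expression on age, sex, BMI, cohort and measured cell-type
# proportions, and quantify how much of the transcriptome tracks cell
# composition (the motivation for the dual adjusted/unadjusted analysis).
suppressMessages(library(netdriver))

run <- file.path("results", "run")
expr <- read_expression(file.path(run, "inputs", "expression.tsv"))
phen <- read_phenotypes(file.path(run, "inputs", "phenotypes.tsv"))

scan <- cell_type_scan(expr, phen)
write_tsv(scan$table, file.path(run, "cell_type_scan.tsv"))
cat(sprintf("%.0f%% of genes associate with cell proportions at Bonferroni p < 0.05.\n",
            100 * scan$fraction_significant))

covs <- c("age", "sex", "bmi", "cohort", grep("^cell_", colnames(phen), value = TRUE))
resid <- residualize(expr, phen, covs)
write_expression(resid, file.path(run, "residuals.tsv"))
cat("Residuals on", paste(covs, collapse = ", "), "written.\n")
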