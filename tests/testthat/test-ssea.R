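# SNP-set enrichment: mapping, LD pruning, the two test statistics,
# permutation calibration, and the multi-set run.

toy_esnp <- function() {
  data.frame(
    snp_id = c("rsA", "rsB", "rsB", "rsC", "rsD"),
    gene_id = c("G1", "G1", "G2", "G3", "G4"),
    kind = c("cis", "trans", "cis", "cis", "cis"),
    eqtl_p = c(1e-6, 1e-4, 1e-5, 1e-3, 1e-2),
    eqtl_fdr = rep(0.01, 5), stringsAsFactors = FALSE)
}

test_that("gene sets map to the union of their eSNPs", {
  es <- toy_esnp()
  snps <- map_geneset_esnps(c("G1", "G2"), es)
  expect_setequal(as.character(snps), c("rsA", "rsB"))   # rsB shared, counted once
  snps2 <- map_geneset_esnps(c("G1", "ABSENT"), es)
  expect_equal(attr(snps2, "genes_without_esnp"), 1L)
  # equals an independent join oracle
  oracle <- unique(merge(data.frame(gene_id = c("G1", "G2")), es)$snp_id)
  expect_setequal(as.character(snps), oracle)
})

test_that("LD pruning follows the greedy best-eQTL rule", {
  ids <- c("rsA", "rsB", "rsC")
  ld1 <- matrix(1, 3, 3, dimnames = list(ids, ids))
  expect_length(ld_prune(ids, ld1, toy_esnp()), 1L)

  ld0 <- diag(3); dimnames(ld0) <- list(ids, ids)
  expect_setequal(ld_prune(ids, ld0, toy_esnp()), ids)

  # chain A-B 0.9, B-C 0.9, A-C 0.5; best eQTL p at B -> only B kept
  ld <- diag(3); dimnames(ld) <- list(ids, ids)
  ld["rsA", "rsB"] <- ld["rsB", "rsA"] <- 0.9
  ld["rsB", "rsC"] <- ld["rsC", "rsB"] <- 0.9
  ld["rsA", "rsC"] <- ld["rsC", "rsA"] <- 0.5
  es <- data.frame(snp_id = ids, gene_id = c("g1", "g2", "g3"),
                   kind = "cis", eqtl_p = c(1e-3, 1e-8, 1e-2),
                   eqtl_fdr = 0.01, stringsAsFactors = FALSE)
  expect_equal(ld_prune(ids, ld, es), "rsB")

  # order invariance
  expect_equal(ld_prune(rev(ids), ld, es), ld_prune(ids, ld, es))
})

test_that("KS enrichment has the stated one-sided behavior", {
  set.seed(3)
  bg <- runif(100)
  expect_equal(as.numeric(ks_enrichment(bg, bg)), 1)
  strong <- rep(1e-9, 100)
  expect_lt(as.numeric(ks_enrichment(strong, bg)), 1e-20)
  p <- ks_enrichment(runif(3), bg)
  expect_true(attr(p, "low_power"))
})

test_that("Fisher enrichment matches closed forms and the fisher.test oracle", {
  # table (10,0 | 0,10): point mass 1 / C(20,10)
  gs <- rep(0.01, 10); bg <- rep(0.5, 10)
  expect_equal(fisher_enrichment(gs, bg), 1 / choose(20, 10), tolerance = 1e-12)

  # no significant SNPs anywhere: p = 1
  expect_equal(fisher_enrichment(rep(0.5, 8), rep(0.6, 12)), 1)

  # random tables agree with stats::fisher.test (the independent route)
  set.seed(8)
  for (i in 1:20) {
    gs <- runif(sample(5:40, 1)); bg <- runif(sample(20:200, 1))
    tab <- matrix(c(sum(gs < 0.05), sum(gs >= 0.05),
                    sum(bg < 0.05), sum(bg >= 0.05)), 2, byrow = TRUE)
    expect_equal(fisher_enrichment(gs, bg),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }

  # matched proportions at large n sit near the null
  set.seed(9)
  p_null <- fisher_enrichment(runif(500), runif(5000))
  expect_gt(p_null, 0.3)
})

test_that("p-values are invariant under background SNP duplication through the chain", {
  cfg <- sim_config(seed = 15)
  gn <- gen_genetics(cfg, gen_expression(cfg)$truth)
  ld <- compute_ld(gn$dosages)
  tr <- gn$truth$true_partition
  sets <- list(test_set = names(tr)[tr == "M1"])
  r1 <- ssea_run(sets, gn$esnp, gn$gwas, ld)
  esnp_dup <- rbind(gn$esnp, transform(gn$esnp, gene_id = paste0(gene_id, "X")))
  r2 <- ssea_run(sets, esnp_dup, gn$gwas, ld)
  expect_equal(r1$p_ks, r2$p_ks, tolerance = 1e-12)
  expect_equal(r1$p_fisher, r2$p_fisher, tolerance = 1e-12)
})

test_that("permutation reporting: worst case 1.0, impossible-to-beat '<0.001'", {
  cfg <- sim_config(seed = 16, n_snps = 1200L)
  cfg$module_spec$size <- c(10L, 10L, 10L, 10L, 5L, 5L)
  cfg$n_null_genes <- 100L
  gn <- gen_genetics(cfg, gen_expression(cfg)$truth)
  ld <- compute_ld(gn$dosages)
  tr <- gn$truth$true_partition
  gene_set <- names(tr)[tr == "M1"]
  obs_best <- list(sbp = c(ks = 0, fisher = 0), dbp = c(ks = 0, fisher = 0))
  pc <- permutation_calibrate(gene_set, gn$esnp, ld, gn$gwas,
                              observed = obs_best, n_perm = 50, seed = 2)
  expect_true(all(pc$perm_count == 0L))
  expect_true(all(pc$perm_p_label == "<0.001"))

  obs_worst <- list(sbp = c(ks = 1.0001, fisher = 1.0001),
                    dbp = c(ks = 1.0001, fisher = 1.0001))
  pc2 <- permutation_calibrate(gene_set, gn$esnp, ld, gn$gwas,
                               observed = obs_worst, n_perm = 50, seed = 2)
  expect_true(all(pc2$perm_p == 1))

  expect_error(permutation_calibrate(paste0("Z", 1:1000), gn$esnp, ld, gn$gwas,
                                     observed = obs_best, n_perm = 5),
               "pool")
})

test_that("planted causal sets beat every permutation", {
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(seed = 20 + s)
    gn <- gen_genetics(cfg, gen_expression(cfg)$truth)
    ld <- compute_ld(gn$dosages)
    tr <- gn$truth$true_partition
    r <- ssea_run(list(M1 = names(tr)[tr == "M1"]), gn$esnp, gn$gwas, ld,
                  n_perm = 200, seed = s)
    all(r$perm_label_ks[r$trait == "SBP"] == "<0.001",
        r$perm_label_fisher[r$trait == "SBP"] == "<0.001")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ssea_run shapes, Bonferroni flags, and causal calls", {
  cfg <- sim_config(seed = 31)
  gn <- gen_genetics(cfg, gen_expression(cfg)$truth)
  ld <- compute_ld(gn$dosages)
  tr <- gn$truth$true_partition
  sets <- split(names(tr)[tr != "null"], tr[tr != "null"])
  set.seed(31); sets$signature <- sample(names(tr)[tr == "null"], 30)
  res <- ssea_run(sets, gn$esnp, gn$gwas, ld)
  expect_equal(nrow(res), 7L * 2L)
  expect_equal(sort(unique(res$gene_set)), sort(names(sets)))
  expect_true(all(res$p_ks_bonf >= res$p_ks, na.rm = TRUE))
  called <- unique(res$gene_set[res$causal_call])
  expect_setequal(called, cfg$causal_modules)

  # a set with no eSNPs is skipped with explicit status
  res2 <- ssea_run(list(empty = c("NOPE1", "NOPE2")), gn$esnp, gn$gwas, ld)
  expect_equal(unique(res2$status), "no_esnps")
  expect_true(all(is.na(res2$p_ks)))
})

test_that("all-null simulations make no causal calls", {
  clean <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = 800 + s, gwas_noncentrality = 0)
    gn <- gen_genetics(cfg, gen_expression(cfg)$truth)
    ld <- compute_ld(gn$dosages)
    tr <- gn$truth$true_partition
    sets <- split(names(tr)[tr != "null"], tr[tr != "null"])
    set.seed(s); sets$signature <- sample(names(tr)[tr == "null"], 30)
    res <- ssea_run(sets, gn$esnp, gn$gwas, ld)
    !any(res$causal_call)
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("analytic and permutation p-values agree in rank across effect sizes", {
  # a ladder weak enough that neither statistic saturates: a 12-gene set
  # under small GWAS non-centralities, with 400 permutations
  cfg <- sim_config(seed = 77)
  ex <- gen_expression(cfg)
  tr <- ex$truth$true_partition
  small_set <- names(tr)[tr == "M1"][1:12]
  analytic <- perm <- numeric(0)
  for (ncp in c(0, 0.25, 0.5, 1, 1.5, 2)) {
    cfgn <- sim_config(seed = 77, gwas_noncentrality = ncp)
    gn <- gen_genetics(cfgn, ex$truth)
    ld <- compute_ld(gn$dosages)
    r <- ssea_run(list(S = small_set), gn$esnp, gn$gwas, ld,
                  n_perm = 400, seed = 7)
    analytic <- c(analytic, r$p_ks[r$trait == "SBP"])
    perm <- c(perm, r$perm_p_ks[r$trait == "SBP"])
  }
  expect_gte(suppressWarnings(cor(analytic, perm, method = "spearman")), 0.9)
})
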