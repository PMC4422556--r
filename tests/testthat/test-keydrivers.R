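# Key-driver analysis: neighborhoods, enrichment, scan, replication, ranking.

test_that("path-graph neighborhoods match hand enumeration", {
  g <- path_graph(5)                       # A-B-C-D-E
  expect_setequal(kd_neighborhood(g, "A", 3), c("B", "C", "D"))
  expect_setequal(kd_neighborhood(g, "C", 1), c("B", "D"))
  iso <- igraph::add_vertices(g, 1, name = "Z")
  expect_length(kd_neighborhood(iso, "Z", 3), 0L)
  expect_error(kd_neighborhood(g, "Q"), "not in network")
})

test_that("neighborhoods equal a breadth-first-search oracle on a random graph", {
  set.seed(21)
  g <- igraph::sample_gnm(200, 400)
  igraph::V(g)$name <- sprintf("N%03d", 1:200)
  bfs_oracle <- function(g, v, depth) {
    d <- igraph::distances(g, v)[1, ]
    names(d)[d >= 1 & d <= depth]
  }
  for (i in 1:50) {
    v <- sample(igraph::V(g)$name, 1)
    depth <- sample(1:3, 1)
    expect_setequal(kd_neighborhood(g, v, depth), bfs_oracle(g, v, depth))
  }
})

test_that("kd_test matches exhaustive enumeration and the fisher.test oracle", {
  set.seed(5)
  g <- igraph::sample_gnm(12, 20)
  igraph::V(g)$name <- LETTERS[1:12]
  gene_set <- c("A", "C", "E", "G")
  for (v in igraph::V(g)$name) {
    r <- kd_test(g, v, gene_set, depth = 2)
    nbhd <- kd_neighborhood(g, v, 2)
    K <- length(setdiff(gene_set, v))
    N <- 11
    expect_equal(r$kd_p, enum_hyper_tail(r$overlap_count, length(nbhd), K, N),
                 tolerance = 1e-10)
    tab <- matrix(c(r$overlap_count, length(nbhd) - r$overlap_count,
                    K - r$overlap_count, N - length(nbhd) - K + r$overlap_count),
                  2, byrow = TRUE)
    expect_equal(r$kd_p, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # degenerate: the gene set is the whole node set
  expect_equal(kd_test(g, "A", igraph::V(g)$name)$kd_p, 1)
})

test_that("a star hub whose leaves are the gene set is the unique key driver", {
  # pad the star with a long tail so the universe is not saturated
  g <- star_graph()
  tail_nodes <- sprintf("T%02d", 1:60)
  g <- igraph::add_vertices(g, 60, name = tail_nodes)
  g <- igraph::add_edges(g, c("L01", "T01",
                              as.vector(rbind(tail_nodes[-60], tail_nodes[-1]))))
  scan <- kd_scan(g, gene_set = sprintf("L%02d", 1:10), depth = 1)
  sig <- scan$gene[scan$significant]
  expect_equal(sig, "HUB")
})

test_that("kd_p is invariant under node relabeling", {
  set.seed(31)
  g <- igraph::sample_gnm(50, 120)
  igraph::V(g)$name <- sprintf("N%02d", 1:50)
  gs <- sample(igraph::V(g)$name, 10)
  s1 <- kd_scan(g, gs)
  perm <- sample(50)
  g2 <- igraph::permute(g, perm)
  s2 <- kd_scan(g2, gs)
  m <- merge(s1, s2, by = "gene")
  expect_equal(m$kd_p.x, m$kd_p.y, tolerance = 1e-12)
})

test_that("planted key drivers are recovered with full precision and recall", {
  prec <- rec <- numeric(6)
  for (s in 1:6) {
    sim_cfg <- sim_config(seed = 900 + s)
    ex <- gen_expression(sim_cfg)
    nt <- gen_network(sim_cfg, ex$truth)
    tr <- nt$truth$true_partition
    sig_all <- character(); hit <- 0
    for (m in sim_cfg$causal_modules) {
      sc <- kd_scan(nt$network, names(tr)[tr == m])
      sig <- sc$gene[sc$significant]
      sig_all <- c(sig_all, sig)
      hit <- hit + (nt$truth$true_kds[[m]] %in% sig)
    }
    rec[s] <- hit / length(sim_cfg$causal_modules)
    prec[s] <- if (length(sig_all))
      sum(sig_all %in% nt$truth$true_kds) / length(sig_all) else NA
  }
  expect_gte(mean(rec), 0.9)
  expect_gte(mean(prec, na.rm = TRUE), 0.8)
})

test_that("random gene-set labels yield no significant key drivers", {
  clean <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = 1100 + s)
    cfg$network$planted_kd_count <- 0L
    ex <- gen_expression(cfg)
    nt <- gen_network(cfg, ex$truth)
    set.seed(s)
    gs <- sample(igraph::V(nt$network)$name, 40)
    sc <- kd_scan(nt$network, gs)
    sum(sc$significant) == 0L
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})

test_that("replication: identity gives 1, degradation is monotone, rewiring kills it", {
  cfg <- sim_config(seed = 42)
  ex <- gen_expression(cfg)
  nt <- gen_network(cfg, ex$truth)
  tr <- nt$truth$true_partition
  gs <- names(tr)[tr == "M1"]
  kds <- kd_scan(nt$network, gs)
  kds <- kds$gene[kds$significant]
  expect_gt(length(kds), 0)

  expect_equal(replicate_kds(kds, nt$network, gs)$fraction, 1)

  drop_frac <- function(g, frac, seed) {
    set.seed(seed)
    ne <- igraph::ecount(g)
    igraph::delete_edges(g, sample(ne, round(frac * ne)))
  }
  fr <- vapply(c(0.2, 0.5, 0.8), function(f) {
    mean(vapply(1:3, function(s)
      replicate_kds(kds, drop_frac(nt$network, f, s), gs)$fraction, 1))
  }, 1)
  expect_true(all(diff(fr) <= 0))

  set.seed(1)
  rewired <- igraph::rewire(nt$network,
                            igraph::keeping_degseq(niter = 10 * igraph::ecount(nt$network)))
  fr_rw <- mean(vapply(1:3, function(s)
    replicate_kds(kds, rewired, gs)$fraction, 1))
  expect_lte(fr_rw, 0.5)
})

test_that("tier ranking orders GWAS, TWAS, MULTI, OTHER correctly", {
  kds <- data.frame(
    gene = c("GW", "TW", "MU", "MU", "OT"),
    network = c("ppi", "ppi", "ppi", "bn", "ppi"),
    kd_p = c(1e-4, 1e-20, 1e-8, 1e-7, 1e-3),
    stringsAsFactors = FALSE)
  esnp <- data.frame(snp_id = c("rs1", "rs2"), gene_id = c("GW", "OT"),
                     kind = "cis", eqtl_p = 1e-6, eqtl_fdr = 0.01,
                     stringsAsFactors = FALSE)
  gwas <- data.frame(snp_id = c("rs1", "rs2"), chr = 1, pos = c(1, 2),
                     p_sbp = c(1.6e-14, 0.3), p_dbp = c(0.5, 0.4),
                     stringsAsFactors = FALSE)
  twas <- data.frame(gene_id = c("TW", "MU"), trait = "SBP", beta = 1, r = 0.3,
                     p = c(4.8e-22, 0.2),
                     bonferroni_significant = c(TRUE, FALSE),
                     stringsAsFactors = FALSE)
  ranked <- rank_kds(kds, esnp, gwas, twas)
  expect_equal(ranked$gene[1], "GW")
  expect_equal(ranked$tier[1], "GWAS")
  expect_equal(ranked$min_esnp_gwas_p[1], 1.6e-14)
  expect_equal(ranked$tier[ranked$gene == "TW"][1], "TWAS")
  expect_true(all(ranked$tier[ranked$gene == "MU"] == "MULTI"))
  expect_equal(ranked$tier[ranked$gene == "OT"], "OTHER")
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  # no tier evidence at all: everything OTHER, sorted by kd_p
  plain <- data.frame(gene = c("B", "A"), kd_p = c(1e-3, 1e-5),
                      stringsAsFactors = FALSE)
  r2 <- rank_kds(plain, esnp[0, ], gwas, twas[0, ])
  expect_equal(r2$gene, c("A", "B"))
  expect_true(all(r2$tier == "OTHER"))
})

test_that("gene-set members can themselves be key drivers", {
  # hub belongs to the set and its leaves are set members too
  g <- star_graph(hub = "GZMB", leaves = sprintf("L%02d", 1:12))
  tail_nodes <- sprintf("T%02d", 1:80)
  g <- igraph::add_vertices(g, 80, name = tail_nodes)
  g <- igraph::add_edges(g, c("L01", "T01",
                              as.vector(rbind(tail_nodes[-80], tail_nodes[-1]))))
  sc <- kd_scan(g, c("GZMB", sprintf("L%02d", 1:12)), depth = 1)
  expect_true("GZMB" %in% sc$gene[sc$significant])
})
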