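# Coexpression network construction, module detection, eigengenes, and the
# module-level association/enrichment/overlap tests.

make_block_data <- function(sizes = c(20, 15, 10), n = 80, noise = 0.05,
                            seed = 1) {
  set.seed(seed)
  G <- sum(sizes)
  labels <- rep(paste0("B", seq_along(sizes)), sizes)
  f <- matrix(rnorm(length(sizes) * n), length(sizes), n)
  m <- t(vapply(seq_len(G), function(g) {
    b <- match(labels[g], paste0("B", seq_along(sizes)))
    f[b, ] + noise * rnorm(n)
  }, numeric(n)))
  dimnames(m) <- list(sprintf("G%03d", seq_len(G)), sprintf("S%03d", seq_len(n)))
  list(expr = m, labels = setNames(labels, rownames(m)))
}

test_that("TOM closed forms hold", {
  # two genes adjacent only to each other with a = 1: w = (0+1)/(1+1-1)
  A <- diag(2); A[1, 2] <- A[2, 1] <- 1
  w <- netdriver:::tom_from_adjacency(A)
  expect_equal(w[1, 2], 1)

  # no off-diagonal adjacency: no overlap
  A0 <- diag(4)
  w0 <- netdriver:::tom_from_adjacency(A0)
  expect_equal(w0[upper.tri(w0)], rep(0, 6))
})

test_that("TOM equals the triple-loop oracle on random fixtures", {
  for (s in 1:3) {
    set.seed(s)
    n <- c(10, 25, 50)[s]
    m <- matrix(rnorm(n * 30), n, 30,
                dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:30)))
    net <- build_network(m, beta = 6)
    expect_lt(max(abs(net$tom - tom_oracle(net$adjacency))), 1e-10)
    expect_equal(net$tom, t(net$tom))
    expect_equal(unname(diag(net$tom)), rep(1, n))
  }
})

test_that("zero-variance genes are rejected by name", {
  m <- tiny_expr(4, 10, seed = 2)
  m[2, ] <- 3
  expect_error(build_network(m, 6), "G02")
})

test_that("soft power selection prefers the smallest passing power", {
  bd <- make_block_data(noise = 0.6, seed = 3)
  fit <- suppressWarnings(pick_soft_power(bd$expr, powers = 1:10))
  expect_true(fit$power %in% 1:10)
  expect_equal(fit$power,
               with(fit$fits, if (any(r2_smooth > 0.8, na.rm = TRUE))
                 min(power[which(r2_smooth > 0.8)]) else
                   power[which.max(r2_smooth)]))
  raw <- suppressWarnings(pick_soft_power(bd$expr, powers = 1:10,
                                          smooth = FALSE))
  expect_equal(raw$power,
               with(raw$fits, if (any(r2 > 0.8, na.rm = TRUE))
                 min(power[which(r2 > 0.8)]) else power[which.max(r2)]))
  # near-orthonormal noise genes: connectivity nearly flat, poor fit at beta 1
  set.seed(5)
  noise <- matrix(rnorm(60 * 200), 60, 200,
                  dimnames = list(sprintf("n%02d", 1:60), sprintf("s%03d", 1:200)))
  fits <- suppressWarnings(pick_soft_power(noise, powers = 1))
  expect_lt(fits$fits$r2[1], 0.8)
})

test_that("separable blocks are recovered exactly and grey absorbs leftovers", {
  bd <- make_block_data(sizes = c(20, 15, 12), noise = 0.02, seed = 7)
  net <- build_network(bd$expr, 6)
  part <- detect_modules(net, min_size = 10)
  expect_equal(adjusted_rand_index(part$labels, bd$labels), 1)
  expect_false(any(part$labels == "grey"))

  # min_size larger than every block: everything grey
  part2 <- detect_modules(net, min_size = 30)
  expect_true(all(part2$labels == "grey"))
  expect_error(detect_modules(net, min_size = 1000),
               class = "netdriver_config_error")
})

test_that("module detection is invariant under gene permutation", {
  bd <- make_block_data(sizes = c(15, 12, 10), noise = 0.3, seed = 9)
  net <- build_network(bd$expr, 6)
  p1 <- detect_modules(net, min_size = 8)
  set.seed(1); perm <- sample(nrow(bd$expr))
  net2 <- build_network(bd$expr[perm, ], 6)
  p2 <- detect_modules(net2, min_size = 8)
  expect_equal(adjusted_rand_index(p1$labels[names(p2$labels)], p2$labels), 1)
})

test_that("module recovery from the default generator reaches ARI 0.8", {
  aris <- vapply(1:5, function(s) {
    sim <- gen_expression(sim_config(seed = s))
    covs <- c("age", "sex", "bmi", "cohort",
              grep("^cell_", colnames(sim$phen), value = TRUE))
    res <- suppressMessages(residualize(sim$expr, sim$phen, covs))
    fit <- suppressWarnings(pick_soft_power(res, powers = 1:10))
    part <- detect_modules(build_network(res, fit$power))
    adjusted_rand_index(part$labels, sim$truth$true_partition)
  }, 1)
  expect_true(all(aris >= 0.8))
})

test_that("eigengenes match the eigendecomposition oracle and orientation rules", {
  bd <- make_block_data(sizes = c(20, 15), noise = 0.4, seed = 13)
  eig <- module_eigengenes(bd$expr, bd$labels)

  # oracle: leading eigenvector of the standardized block's sample covariance
  sub <- t(scale(t(bd$expr[names(bd$labels)[bd$labels == "B1"], ])))
  ev <- eigen(crossprod(sub))
  cosang <- abs(sum(eig$eigengenes["B1", ] * ev$vectors[, 1]))
  expect_gte(cosang, 1 - 1e-8)
  expect_equal(eig$variance_explained[["B1"]],
               ev$values[1] / sum(ev$values), tolerance = 1e-8)

  # identical genes: variance explained 1, eigengene tracks the shared profile
  m <- matrix(rep(rnorm(30), each = 5), 5, 30,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:30)))
  e2 <- module_eigengenes(m, setNames(rep("mod", 5), rownames(m)))
  expect_equal(e2$variance_explained[["mod"]], 1)
  expect_gt(cor(e2$eigengenes["mod", ], m[1, ]), 0.999)

  # flipping all member genes flips nothing observable
  e3 <- module_eigengenes(-m, setNames(rep("mod", 5), rownames(m)))
  expect_gt(cor(e3$eigengenes["mod", ], -m[1, ]), 0.999)

  # unit-norm rows; mean member correlation non-negative
  expect_equal(sum(eig$eigengenes["B1", ]^2), 1, tolerance = 1e-10)
  expect_gte(mean(cor(t(sub), eig$eigengenes["B1", ])), 0)
})

test_that("module-trait association flags and FDR behave", {
  ph <- tiny_phen(sprintf("S%03d", 1:100), seed = 17)
  E <- rbind(hit = as.numeric(scale(ph$sbp)), null = rnorm(100))
  E <- E / sqrt(rowSums(E^2))
  colnames(E) <- ph$sample_id
  mt <- module_trait(E, ph)
  hit_sbp <- mt[mt$module == "hit" & mt$trait == "SBP", ]
  expect_gt(hit_sbp$r, 0.999)
  expect_lt(hit_sbp$p, 1e-12)
  expect_true(all(mt$fdr >= mt$p))
  expect_equal(unname(attr(mt, "min_p")["hit"]), min(mt$p[mt$module == "hit"]))
})

test_that("null module-trait significance count matches its expectation", {
  counts <- vapply(1:40, function(s) {
    set.seed(500 + s)
    ph <- tiny_phen(sprintf("S%03d", 1:100), seed = 500 + s)
    E <- matrix(rnorm(27 * 100), 27, 100,
                dimnames = list(sprintf("m%02d", 1:27), ph$sample_id))
    mt <- module_trait(E, ph)
    sum(mt$p < 0.05)
  }, 1)
  # expectation 0.05 * 27 * 2 = 2.7 (traits correlated, so variance is wide)
  expect_lt(abs(mean(counts) - 2.7), 1)
})

test_that("signature enrichment reproduces a hand-enumerated tail on a toy", {
  labels <- setNames(c(rep("mod1", 5), rep("mod2", 7), rep("grey", 8)),
                     sprintf("G%02d", 1:20))
  signature <- c(sprintf("G%02d", 1:4), "G18")   # 4 in mod1, 1 in grey
  res <- module_signature_enrichment(labels, signature)
  r1 <- res[res$module == "mod1", ]
  expect_equal(unlist(r1[, c("k", "n", "K", "N")], use.names = FALSE),
               c(4, 5, 5, 20))
  expect_equal(r1$p, enum_hyper_tail(4, 5, 5, 20), tolerance = 1e-12)

  # constructed containment: signature inside one small module
  labels2 <- setNames(c(rep("m1", 6), rep("m2", 30), rep("grey", 64)),
                      sprintf("H%03d", 1:100))
  res2 <- module_signature_enrichment(labels2, sprintf("H%03d", 1:6))
  expect_lt(res2$p[res2$module == "m1"], 1e-6)
  expect_gt(res2$p[res2$module == "m2"], 0.05)
})

test_that("random signatures rarely enrich any module", {
  hits <- vapply(1:10, function(s) {
    set.seed(600 + s)
    labels <- setNames(sample(c(paste0("m", 1:5), "grey"), 300, TRUE),
                       sprintf("g%03d", 1:300))
    sig <- sample(names(labels), 25)
    res <- module_signature_enrichment(labels, sig)
    min(res$p) < 0.05 / nrow(res)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("module overlap finds identity conservation and constructed splits", {
  labels <- setNames(c(rep("a1", 30), rep("a2", 25), rep("a3", 20)),
                     sprintf("g%03d", 1:75))
  ov <- module_overlap(labels, labels)
  expect_equal(nrow(ov$conserved), 3L)
  expect_true(all(ov$conserved$a == ov$conserved$b))

  split_labels <- labels
  split_labels[1:15] <- "b1x"; split_labels[16:30] <- "b1y"
  ov2 <- module_overlap(labels, split_labels)
  expect_true("a1" %in% names(ov2$splits))
  expect_setequal(ov2$splits[["a1"]], c("b1x", "b1y"))

  # independent random partitions: no conserved pairs after correction
  none <- vapply(1:10, function(s) {
    set.seed(700 + s)
    la <- setNames(sample(paste0("a", 1:4), 200, TRUE), sprintf("g%03d", 1:200))
    lb <- setNames(sample(paste0("b", 1:4), 200, TRUE), sprintf("g%03d", 1:200))
    nrow(module_overlap(la, lb)$conserved) == 0L
  }, logical(1))
  expect_gte(mean(none), 0.95)
})
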