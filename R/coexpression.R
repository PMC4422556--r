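# Weighted coexpression network construction, module detection, eigengenes,
# module-trait association, signature enrichment, and cross-network module
# overlap.
#
# The network is unsigned: adjacency a_ij = |cor(x_i, x_j)|^beta. Gene pairs
# are clustered on the topological overlap of their connectivity,
#   w_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
#   l_ij = sum_{u != i,j} a_iu a_uj,   k_i = sum_{u != i} a_iu,
# which credits two genes both for direct adjacency and for sharing
# neighbors, yielding more coherent modules than raw correlation clustering.

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power, builds the unsigned adjacency, computes node
#' connectivity k, bins k into `n_bins` equal-width bins, and regresses
#' log10 frequency on log10 bin-center connectivity over occupied bins. The
#' selected power is the smallest whose fit R-squared exceeds `r2_threshold`
#' (a perfectly scale-free network has R-squared 1); if none qualifies the
#' power with the best fit is returned with a warning. On networks of a few
#' hundred genes the per-power binned R-squared is noisy, so by default the
#' selection statistic is a 3-point running mean of the R-squared curve
#' over the scanned ladder — an isolated lucky fit at a too-low power
#' would otherwise be chosen and dissolve downstream module detection
#' (`smooth = FALSE` restores the raw rule).
#'
#' @param resid genes x samples residual matrix (>= 30 genes).
#' @param powers candidate integer powers.
#' @param r2_threshold scale-free fit threshold (default 0.8).
#' @param n_bins connectivity histogram bins (default 10).
#' @param smooth apply the 3-point running mean before selection.
#' @return list with `power` (selected), `fits` (data.frame power, r2,
#'   r2_smooth, mean_k), `selected_by_threshold` flag.
#' @export
pick_soft_power <- function(resid, powers = 1:20, r2_threshold = 0.8,
                            n_bins = 10L, smooth = TRUE) {
  if (nrow(resid) < 30L) nd_stop("pick_soft_power needs >= 30 genes")
  cmat <- abs(stats::cor(t(resid)))
  fits <- data.frame(power = powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    A <- cmat^powers[[i]]
    k <- rowSums(A) - 1
    fits$mean_k[i] <- mean(k)
    fits$r2[i] <- scale_free_r2(k, n_bins)
  }
  fits$r2_smooth <- if (smooth && length(powers) > 1L) {
    vapply(seq_along(powers), function(i)
      mean(fits$r2[max(1L, i - 1L):min(length(powers), i + 1L)], na.rm = TRUE),
      1)
  } else fits$r2
  crit <- fits$r2_smooth
  ok <- which(!is.na(crit) & crit > r2_threshold)
  if (length(ok)) {
    sel <- powers[min(ok)]
    by_thr <- TRUE
  } else {
    warning("pick_soft_power: no power reaches the fit threshold; using best fit")
    sel <- powers[which.max(crit)]
    by_thr <- FALSE
  }
  list(power = sel, fits = fits, selected_by_threshold = by_thr,
       r2_threshold = r2_threshold)
}

# R-squared of log10 p(k) vs log10 k over occupied equal-width bins.
scale_free_r2 <- function(k, n_bins = 10L) {
  if (stats::sd(k) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- as.numeric(table(bin))
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  keep <- freq > 0 & mids > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm(log10(freq[keep]) ~ log10(mids[keep]))
  summary(fit)$r.squared
}

#' Build the unsigned coexpression network (adjacency and TOM)
#'
#' @param resid genes x samples matrix; every gene must vary.
#' @param beta soft-thresholding power (>= 1).
#' @return list with `adjacency` and `tom` (symmetric genes x genes matrices
#'   with unit diagonal) plus `gene_ids`.
#' @export
build_network <- function(resid, beta) {
  stopifnot(beta >= 1)
  sds <- apply(resid, 1L, stats::sd)
  if (any(sds == 0))
    nd_stop(paste("zero-variance gene(s):",
                  paste(utils::head(rownames(resid)[sds == 0], 5L), collapse = ", ")))
  A <- abs(stats::cor(t(resid)))^beta
  diag(A) <- 1
  tom <- tom_from_adjacency(A)
  list(adjacency = A, tom = tom, gene_ids = rownames(resid), beta = beta)
}

# Topological overlap from an adjacency with unit diagonal, in matrix form:
# with diag(A)=1, (A %*% A)_ij = l_ij + 2 a_ij, so l = A^2 - 2A off-diagonal.
tom_from_adjacency <- function(A) {
  k <- rowSums(A) - 1
  L <- A %*% A - 2 * A            # l_ij off-diagonal; diagonal unused
  denom <- outer(k, k, pmin) + 1 - A
  w <- (L + A) / denom
  diag(w) <- 1
  dimnames(w) <- dimnames(A)
  w
}

#' Detect modules by average-linkage clustering of topological overlap
#'
#' Genes are clustered on dissimilarity 1 - TOM with average linkage and the
#' dendrogram cut at `cut_height_frac` of its maximum merge height; every
#' resulting branch with at least `min_size` genes becomes a module. With
#' `deep_split`, each module is re-examined once: its sub-dendrogram is cut
#' at the largest internal gap between consecutive merge heights, and the
#' split is kept only when every resulting piece still has `min_size` genes.
#' Unassigned genes are labeled `"grey"`; module labels are colors assigned
#' by decreasing size.
#'
#' @param net output of [build_network()].
#' @param min_size minimum module size (default 30).
#' @param cut_height_frac static cut height as a fraction of the maximum
#'   merge height (default 0.99).
#' @param deep_split re-cut branches at their maximal internal gap once
#'   (default TRUE).
#' @return list with `labels` (named character vector gene -> color),
#'   `sizes`, and the `hclust` object.
#' @export
detect_modules <- function(net, min_size = 30L, cut_height_frac = 0.99,
                           deep_split = TRUE) {
  genes <- net$gene_ids
  if (min_size > length(genes))
    nd_stop("min_size exceeds gene count", "netdriver_config_error")
  d <- stats::as.dist(1 - net$tom)
  hc <- stats::hclust(d, method = "average")
  cut_h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = cut_h)
  groups <- split(genes, cl)
  modules <- list()
  for (grp in groups) {
    if (length(grp) < min_size) next
    pieces <- list(grp)
    if (deep_split && length(grp) >= 2L * min_size) {
      pieces <- gap_split(grp, net$tom, min_size)
    }
    modules <- c(modules, pieces)
  }
  labels <- rep("grey", length(genes))
  names(labels) <- genes
  if (length(modules)) {
    ord <- order(lengths(modules), decreasing = TRUE)
    modules <- modules[ord]
    cols <- MODULE_COLORS[((seq_along(modules) - 1L) %% length(MODULE_COLORS)) + 1L]
    for (i in seq_along(modules)) labels[modules[[i]]] <- cols[[i]]
  }
  sizes <- sort(table(labels[labels != "grey"]), decreasing = TRUE)
  list(labels = labels, sizes = sizes, hclust = hc, cut_height = cut_h)
}

# One-shot re-split of a branch at its maximal internal merge-height gap;
# keeps the split only if all pieces reach min_size.
gap_split <- function(genes, tom, min_size) {
  sub <- stats::hclust(stats::as.dist(1 - tom[genes, genes, drop = FALSE]),
                       method = "average")
  h <- sort(sub$height)
  if (length(h) < 2L) return(list(genes))
  gaps <- diff(h)
  cut_at <- (h[which.max(gaps)] + h[which.max(gaps) + 1L]) / 2
  cl <- stats::cutree(sub, h = cut_at)
  pieces <- split(genes, cl)
  if (length(pieces) >= 2L && all(lengths(pieces) >= min_size)) pieces
  else list(genes)
}

#' Module eigengenes and variance explained
#'
#' The eigengene of a module is the first right singular vector of the
#' gene-standardized member submatrix across samples (the module's first
#' principal component), sign-oriented so its mean correlation with member
#' genes is non-negative. Variance explained is the first squared singular
#' value over the total.
#'
#' @param resid genes x samples matrix.
#' @param labels named gene -> module vector ("grey" skipped).
#' @return list with `eigengenes` (modules x samples, unit-norm rows) and
#'   `variance_explained`.
#' @export
module_eigengenes <- function(resid, labels) {
  labels <- labels[names(labels) %in% rownames(resid)]
  mods <- setdiff(unique(labels), "grey")
  mods <- names(sort(table(labels[labels %in% mods]), decreasing = TRUE))
  E <- matrix(NA_real_, length(mods), ncol(resid),
              dimnames = list(mods, colnames(resid)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    sub <- resid[names(labels)[labels == m], , drop = FALSE]
    sub <- t(scale(t(sub)))
    sv <- svd(sub, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    if (mean(stats::cor(t(sub), v)) < 0) v <- -v
    E[m, ] <- v
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, variance_explained = ve)
}

#' Associate module eigengenes with blood-pressure traits
#'
#' Pearson correlation with a two-sided t-test per module x trait, BH FDR
#' across all pairs, with the significance tiers used for reporting
#' (p < 0.05, FDR < 0.2, FDR < 0.05). A module's headline association is
#' its minimum p over the tested traits.
#'
#' @param eigengenes modules x samples matrix.
#' @param phen phenotype data.frame.
#' @param traits trait columns to test (default SBP and DBP).
#' @return data.frame module, trait, r, p, fdr, sig_p05, sig_fdr20,
#'   sig_fdr05, plus attribute `"min_p"` (named per-module minimum p).
#' @export
module_trait <- function(eigengenes, phen, traits = c("sbp", "dbp")) {
  phen <- phen[match(colnames(eigengenes), phen$sample_id), , drop = FALSE]
  n <- ncol(eigengenes)
  rows <- list()
  for (trait in traits) {
    y <- as.numeric(phen[[trait]])
    r <- as.numeric(stats::cor(t(eigengenes), y))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- pmin(1, 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE))
    rows[[trait]] <- data.frame(module = rownames(eigengenes),
                                trait = toupper(trait), r = r, p = p,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$sig_p05 <- out$p < 0.05
  out$sig_fdr20 <- out$sig_p05 & out$fdr < 0.2
  out$sig_fdr05 <- out$fdr < 0.05
  rownames(out) <- NULL
  minp <- vapply(split(out$p, out$module), min, 1)
  attr(out, "min_p") <- minp
  out
}

#' Enrichment of a signature gene set in each module
#'
#' One-sided Fisher test of module membership against signature membership.
#' The universe is every partitioned gene (grey genes included in the
#' universe but never as a module).
#'
#' @param labels named gene -> module vector.
#' @param signature character vector of signature genes.
#' @return data.frame module, k, n, K, N, fold, p.
#' @export
module_signature_enrichment <- function(labels, signature) {
  universe <- names(labels)
  signature <- intersect(signature, universe)
  mods <- setdiff(unique(labels), "grey")
  N <- length(universe); K <- length(signature)
  res <- lapply(mods, function(m) {
    members <- names(labels)[labels == m]
    k <- length(intersect(members, signature))
    n <- length(members)
    data.frame(module = m, k = k, n = n, K = K, N = N,
               fold = fold_enrichment(k, n, K, N),
               p = hyper_p(k, n, K, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p), , drop = FALSE]
}

#' Cross-partition module overlap, conservation, and splits
#'
#' Fisher overlap for every module pair across two partitions (universe =
#' genes present in both), Bonferroni-corrected over pairs. A module pair is
#' "conserved" when it is Bonferroni-significant and each member is the
#' other's best match (best reciprocal match). A module of A "splits" in B
#' when it significantly matches two or more B modules.
#'
#' @param labels_a,labels_b named gene -> module vectors.
#' @return list with `pairs` (data.frame), `conserved` (data.frame a, b),
#'   `splits` (named list a-module -> b-modules).
#' @export
module_overlap <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  la <- labels_a[common]; lb <- labels_b[common]
  mods_a <- setdiff(unique(la), "grey"); mods_b <- setdiff(unique(lb), "grey")
  N <- length(common)
  grid <- expand.grid(a = mods_a, b = mods_b, stringsAsFactors = FALSE)
  grid$k <- grid$n <- grid$K <- grid$p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    ga <- common[la == grid$a[i]]; gb <- common[lb == grid$b[i]]
    grid$k[i] <- length(intersect(ga, gb))
    grid$n[i] <- length(ga); grid$K[i] <- length(gb)
    grid$p[i] <- hyper_p(grid$k[i], grid$n[i], grid$K[i], N)
  }
  m <- nrow(grid)
  grid$p_bonf <- pmin(1, grid$p * m)
  grid$significant <- grid$p_bonf < 0.05
  best_a <- tapply(seq_len(nrow(grid)), grid$a, function(i) grid$b[i][which.min(grid$p[i])])
  best_b <- tapply(seq_len(nrow(grid)), grid$b, function(i) grid$a[i][which.min(grid$p[i])])
  conserved <- grid[grid$significant &
                      grid$b == unlist(best_a[grid$a]) &
                      grid$a == unlist(best_b[grid$b]), c("a", "b"), drop = FALSE]
  sig_by_a <- split(grid$b[grid$significant], grid$a[grid$significant])
  splits <- Filter(function(x) length(x) >= 2L, sig_by_a)
  list(pairs = grid, conserved = conserved, splits = splits)
}
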