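# SNP-set enrichment analysis (SSEA): does a gene set's eSNPs carry
# systematically smaller trait-GWAS p-values than the background of all
# eSNPs? Chain: map gene set -> eSNPs, LD-prune at r2 >= 0.8, compare the
# pruned set's GWAS p-values to the pruned background with a one-sided
# Kolmogorov-Smirnov test and a one-sided Fisher test on the p < 0.05
# dichotomy, calibrate by size-matched gene-set permutations, and
# Bonferroni-correct across the tested gene sets.

#' Per-SNP ranking p-value for LD pruning
#'
#' A SNP's rank is its smallest eQTL p over all genes it regulates.
#'
#' @param esnp eSNP table.
#' @return named numeric vector snp_id -> rank p.
#' @export
snp_rank_p <- function(esnp) {
  ord <- order(esnp$eqtl_p)
  first <- !duplicated(esnp$snp_id[ord])
  stats::setNames(esnp$eqtl_p[ord][first], esnp$snp_id[ord][first])
}

#' Map a gene set to its eSNPs
#'
#' Union of all eSNPs (cis and trans) of the member genes; duplicate SNPs
#' shared by several members appear once.
#'
#' @param gene_set character vector of gene symbols.
#' @param esnp eSNP table (see [read_esnp()]), already FDR-filtered.
#' @return character vector of SNP ids (possibly empty); attribute
#'   `"genes_without_esnp"` counts members with no eSNP.
#' @export
map_geneset_esnps <- function(gene_set, esnp) {
  gene_set <- unique(norm_symbol(gene_set))
  hit <- esnp[esnp$gene_id %in% gene_set, , drop = FALSE]
  snps <- unique(hit$snp_id)
  missing <- setdiff(gene_set, hit$gene_id)
  attr(snps, "genes_without_esnp") <- length(missing)
  snps
}

#' Greedy LD pruning of a SNP list
#'
#' SNPs are ranked by eQTL p-value (ascending, ties broken by SNP id) and
#' greedily retained: the best remaining SNP is kept and every remaining SNP
#' with r2 >= `r2_threshold` to it is discarded. Ranking on the eQTL rather
#' than the GWAS p-value keeps the selection blind to the association signal
#' being tested, so the null is unbiased. Output is deterministic and
#' independent of input order.
#'
#' @param snps character vector of SNP ids.
#' @param ld r2 matrix (SNP ids in dimnames); pairs absent from the matrix
#'   are treated as unlinked.
#' @param esnp eSNP table supplying the eQTL p ranking (a SNP's rank p is
#'   its smallest eqtl_p over genes), or a precomputed named vector from
#'   `snp_rank_p()`; SNPs absent rank last.
#' @param r2_threshold prune threshold (default 0.8).
#' @return pruned SNP id vector, in kept order.
#' @export
ld_prune <- function(snps, ld, esnp = NULL, r2_threshold = 0.8) {
  snps <- unique(snps)
  if (!length(snps)) return(character())
  rank_p <- rep(1, length(snps))
  if (!is.null(esnp)) {
    agg <- if (is.numeric(esnp)) esnp else snp_rank_p(esnp)
    hit <- match(snps, names(agg))
    rank_p[!is.na(hit)] <- agg[hit[!is.na(hit)]]
  }
  ord <- order(rank_p, snps, method = "radix")
  queue <- snps[ord]
  pos <- match(queue, rownames(ld))          # NA: SNP unknown to the LD panel
  known <- which(!is.na(pos))
  sub <- if (length(known))
    ld[pos[known], pos[known], drop = FALSE] else NULL
  sub_idx <- rep(NA_integer_, length(queue))
  sub_idx[known] <- seq_along(known)
  alive <- rep(TRUE, length(queue))
  for (i in seq_along(queue)) {
    if (!alive[i]) next
    si <- sub_idx[i]
    if (!is.na(si)) {
      later <- which(alive & !is.na(sub_idx) & seq_along(queue) > i)
      if (length(later))
        alive[later[sub[si, sub_idx[later]] >= r2_threshold]] <- FALSE
    }
  }
  queue[alive]
}

#' One-sided KS enrichment of a gene set's GWAS p-values
#'
#' Two-sample Kolmogorov-Smirnov test with the one-sided alternative that
#' the gene-set p-values are stochastically smaller than the background
#' (their empirical CDF lies above the background CDF). The exact
#' conditional null distribution of the one-sided statistic is used at
#' these sample sizes; the classical asymptotic tail is visibly
#' conservative in the mid-range, which matters for permutation-free
#' calibration checks.
#'
#' @param geneset_p GWAS p-values of the (pruned) gene-set eSNPs.
#' @param background_p GWAS p-values of the (pruned) background eSNPs.
#' @return KS p-value; attribute `"low_power"` set when the gene-set list
#'   has fewer than 5 SNPs.
#' @export
ks_enrichment <- function(geneset_p, background_p) {
  if (!length(geneset_p) || !length(background_p))
    nd_stop("ks_enrichment: empty p-value list")
  p <- suppressWarnings(
    stats::ks.test(geneset_p, background_p, alternative = "greater",
                   exact = TRUE)$p.value)
  p <- min(max(p, 0), 1)
  attr(p, "low_power") <- length(geneset_p) < 5L
  p
}

#' One-sided Fisher enrichment on the GWAS significance dichotomy
#'
#' All eSNPs are dichotomized at GWAS p < `gwas_alpha`; the 2x2 table
#' {gene set vs background} x {significant vs not} is tested one-sided for
#' excess significant SNPs in the gene set.
#'
#' @inheritParams ks_enrichment
#' @param gwas_alpha dichotomy threshold (default 0.05).
#' @return Fisher p-value.
#' @export
fisher_enrichment <- function(geneset_p, background_p, gwas_alpha = 0.05) {
  if (!length(geneset_p) || !length(background_p))
    nd_stop("fisher_enrichment: empty p-value list")
  a <- sum(geneset_p < gwas_alpha); b <- length(geneset_p) - a
  c_ <- sum(background_p < gwas_alpha); d <- length(background_p) - c_
  # one-sided Fisher p for the 2x2 table (a b / c d) is the upper
  # hypergeometric tail at fixed margins
  stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
}

# Run map -> prune -> (KS, Fisher per trait) for one gene set. gwas_p is a
# named list trait -> named numeric vector of p-values keyed by snp_id.
ssea_one <- function(gene_set, esnp, ld, gwas_p, background,
                     r2_threshold = 0.8, gwas_alpha = 0.05,
                     snp_rank = NULL) {
  snps_raw <- map_geneset_esnps(gene_set, esnp)
  if (!length(snps_raw)) {
    return(list(status = "no_esnps", n_raw = 0L, n_pruned = 0L,
                p = lapply(gwas_p, function(.) c(ks = NA_real_, fisher = NA_real_))))
  }
  if (is.null(snp_rank)) snp_rank <- snp_rank_p(esnp)
  pruned <- ld_prune(snps_raw, ld, snp_rank, r2_threshold)
  # the tested set's SNPs are held out of the background: keeping them
  # nested makes the two samples dependent and the null conservative at
  # this scale, where a set can be a sizable fraction of all eSNPs
  bg_snps <- setdiff(background, snps_raw)
  p <- lapply(gwas_p, function(pv) {
    gs <- pv[pruned]; gs <- gs[!is.na(gs)]
    bg <- pv[bg_snps]; bg <- bg[!is.na(bg)]
    c(ks = as.numeric(ks_enrichment(gs, bg)),
      fisher = fisher_enrichment(gs, bg, gwas_alpha))
  })
  list(status = "ok", n_raw = length(snps_raw), n_pruned = length(pruned), p = p)
}

#' Permutation calibration of SSEA p-values
#'
#' Each of `n_perm` permutations draws a random gene set of matching size
#' from the pool of genes having at least one eSNP and runs the identical
#' map -> prune -> test chain. The empirical p is the number of permutation
#' sets with an analytic p strictly less than the observed, divided by
#' `n_perm`; a zero count is reported as `"<0.001"` at the default 1,000
#' permutations.
#'
#' @param gene_set character vector of member genes.
#' @param esnp,ld,gwas,traits as in [ssea_run()].
#' @param observed named list trait -> c(ks, fisher) analytic p-values.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for the permutation draws.
#' @param r2_threshold,gwas_alpha as in [ssea_run()].
#' @return data.frame trait, test, perm_count, perm_p, perm_p_label.
#' @export
permutation_calibrate <- function(gene_set, esnp, ld, gwas,
                                  traits = c("sbp", "dbp"), observed,
                                  n_perm = 1000L, seed = 1L,
                                  r2_threshold = 0.8, gwas_alpha = 0.05) {
  pool <- unique(esnp$gene_id)
  k <- length(unique(norm_symbol(gene_set)))
  if (length(pool) < k)
    nd_stop("permutation_calibrate: gene pool smaller than the tested set")
  gwas_p <- gwas_p_lookup(gwas, traits)
  snp_rank <- snp_rank_p(esnp)
  background <- ld_prune(unique(esnp$snp_id), ld, snp_rank, r2_threshold)
  set.seed(seed)
  counts <- matrix(0L, length(traits), 2L,
                   dimnames = list(traits, c("ks", "fisher")))
  for (b in seq_len(n_perm)) {
    draw <- resample(pool, k)
    res <- ssea_one(draw, esnp, ld, gwas_p, background, r2_threshold,
                    gwas_alpha, snp_rank)
    for (tr in traits) {
      for (test in c("ks", "fisher")) {
        obs <- observed[[tr]][[test]]
        if (!is.na(obs) && !is.na(res$p[[tr]][[test]]) &&
            res$p[[tr]][[test]] < obs)
          counts[tr, test] <- counts[tr, test] + 1L
      }
    }
  }
  out <- expand.grid(trait = traits, test = c("ks", "fisher"),
                     stringsAsFactors = FALSE)
  out$perm_count <- counts[cbind(out$trait, out$test)]
  out$perm_p <- out$perm_count / n_perm
  out$perm_p_label <- fmt_perm_p(out$perm_count, n_perm)
  out
}

gwas_p_lookup <- function(gwas, traits) {
  lapply(stats::setNames(traits, traits), function(tr) {
    col <- paste0("p_", tr)
    if (!col %in% colnames(gwas)) nd_stop(paste("GWAS table lacks column", col))
    stats::setNames(gwas[[col]], gwas$snp_id)
  })
}

#' Run SNP-set enrichment analysis over a gene-set collection
#'
#' For every gene set and trait, computes the analytic one-sided KS and
#' Fisher enrichment p-values of the set's LD-pruned eSNP GWAS p-values
#' against the LD-pruned background of all eSNPs, optionally calibrates
#' them with size-matched permutations, Bonferroni-corrects across gene
#' sets, and calls a set "genetically inferred causal" when both corrected
#' analytic tests pass at 0.05 for at least one trait.
#'
#' @param gene_sets named list of gene symbol vectors.
#' @param esnp eSNP table (FDR-filtered).
#' @param gwas GWAS summary table with `p_<trait>` columns.
#' @param ld r2 matrix.
#' @param traits traits to test (default sbp, dbp).
#' @param n_perm permutations per set and test (0 skips calibration).
#' @param seed RNG seed for permutations.
#' @param r2_threshold LD prune threshold (default 0.8).
#' @param gwas_alpha Fisher dichotomy threshold (default 0.05).
#' @param alpha family-wise alpha for the causal call (default 0.05).
#' @return data.frame, one row per gene set x trait, with analytic and
#'   permutation p-values, Bonferroni flags, and the per-set `causal_call`.
#' @export
ssea_run <- function(gene_sets, esnp, gwas, ld, traits = c("sbp", "dbp"),
                     n_perm = 0L, seed = 1L, r2_threshold = 0.8,
                     gwas_alpha = 0.05, alpha = 0.05) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  m <- length(gene_sets)
  gwas_p <- gwas_p_lookup(gwas, traits)
  snp_rank <- snp_rank_p(esnp)
  background <- ld_prune(unique(esnp$snp_id), ld, snp_rank, r2_threshold)
  rows <- list()
  for (nm in names(gene_sets)) {
    res <- ssea_one(gene_sets[[nm]], esnp, ld, gwas_p, background,
                    r2_threshold, gwas_alpha, snp_rank)
    perm <- NULL
    if (n_perm > 0L && res$status == "ok") {
      perm <- permutation_calibrate(
        gene_sets[[nm]], esnp, ld, gwas, traits, res$p,
        n_perm = n_perm, seed = stage_seed(seed, paste0("perm_", nm)),
        r2_threshold = r2_threshold, gwas_alpha = gwas_alpha)
    }
    for (tr in traits) {
      pk <- res$p[[tr]][["ks"]]; pf <- res$p[[tr]][["fisher"]]
      row <- data.frame(
        gene_set = nm, trait = toupper(tr), status = res$status,
        n_esnps_raw = res$n_raw, n_esnps_pruned = res$n_pruned,
        p_ks = pk, p_fisher = pf,
        p_ks_bonf = pmin(1, pk * m), p_fisher_bonf = pmin(1, pf * m),
        stringsAsFactors = FALSE)
      if (!is.null(perm)) {
        pr <- perm[perm$trait == tr, , drop = FALSE]
        row$perm_p_ks <- pr$perm_p[pr$test == "ks"]
        row$perm_p_fisher <- pr$perm_p[pr$test == "fisher"]
        row$perm_label_ks <- pr$perm_p_label[pr$test == "ks"]
        row$perm_label_fisher <- pr$perm_p_label[pr$test == "fisher"]
      } else {
        row$perm_p_ks <- row$perm_p_fisher <- NA_real_
        row$perm_label_ks <- row$perm_label_fisher <- NA_character_
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out$both_pass <- !is.na(out$p_ks_bonf) & !is.na(out$p_fisher_bonf) &
    out$p_ks_bonf < alpha & out$p_fisher_bonf < alpha
  call_by_set <- tapply(out$both_pass, out$gene_set, any)
  out$causal_call <- as.logical(call_by_set[out$gene_set])
  rownames(out) <- NULL
  out
}
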