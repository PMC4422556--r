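# Key-driver analysis: find network nodes whose 1st-3rd-layer neighborhood
# is enriched for members of a trait-associated ("causal") gene set, rank
# them by orthogonal genetic and transcriptomic evidence, and test
# replication across an independent network.

#' Depth-limited network neighborhood of a node
#'
#' All nodes within graph distance `depth` of `node`, excluding the node
#' itself (layer 1 = direct neighbors, layer 2 = their neighbors, layer 3 =
#' those nodes' neighbors). Directed networks are expanded ignoring edge
#' orientation by default.
#'
#' @param net igraph graph.
#' @param node node name.
#' @param depth maximum distance (default 3).
#' @param mode igraph expansion mode for directed graphs (default "all").
#' @return character vector of node names.
#' @export
kd_neighborhood <- function(net, node, depth = 3L, mode = "all") {
  if (!node %in% igraph::V(net)$name)
    nd_stop(paste("node not in network:", node))
  nb <- igraph::ego(net, order = depth, nodes = node, mode = mode,
                    mindist = 1L)[[1L]]
  nb$name
}

#' Key-driver enrichment test for one candidate node
#'
#' One-sided Fisher (hypergeometric) test of the candidate's <=`depth`-layer
#' neighborhood against the gene set, over the universe of all network
#' nodes excluding the candidate itself (the candidate neither counts for
#' nor against its own neighborhood).
#'
#' @param net igraph graph.
#' @param node candidate node name.
#' @param gene_set character vector of gene symbols.
#' @param depth neighborhood depth (default 3).
#' @return list with `overlap_count`, `neighborhood_size`, `kd_p`.
#' @export
kd_test <- function(net, node, gene_set, depth = 3L) {
  nbhd <- kd_neighborhood(net, node, depth)
  universe <- setdiff(igraph::V(net)$name, node)
  set_in_net <- intersect(unique(norm_symbol(gene_set)), universe)
  k <- length(intersect(nbhd, set_in_net))
  list(overlap_count = k,
       neighborhood_size = length(nbhd),
       kd_p = hyper_p(k, length(nbhd), length(set_in_net), length(universe)))
}

#' Scan a network for key drivers of a gene set
#'
#' Candidates are the nodes of the gene set's "3rd-layer expanding network":
#' the union of the <=`depth`-step neighborhoods of the set members present
#' in the network (members included). Every candidate is tested with
#' [kd_test()] and Bonferroni-corrected by the candidate-pool size (the
#' expanding-network correction; set `correct_all_nodes = TRUE` to correct
#' by the full node count instead). Significant candidates are key drivers.
#'
#' @param net igraph graph.
#' @param gene_set character vector of gene symbols.
#' @param alpha family-wise alpha (default 0.05).
#' @param depth neighborhood depth (default 3).
#' @param correct_all_nodes Bonferroni by all network nodes rather than the
#'   candidate pool.
#' @return data.frame of all candidates sorted by kd_p, with
#'   `neighborhood_size`, `overlap_count`, `kd_p`, `kd_p_corrected`,
#'   `significant`; attribute `"n_candidates"` records the correction count.
#' @export
kd_scan <- function(net, gene_set, alpha = 0.05, depth = 3L,
                    correct_all_nodes = FALSE) {
  nodes <- igraph::V(net)$name
  members <- intersect(unique(norm_symbol(gene_set)), nodes)
  if (!length(members))
    return(structure(data.frame(), status = "gene set absent from network"))
  pool <- unique(unlist(lapply(
    igraph::ego(net, order = depth, nodes = members, mindist = 0L),
    function(v) v$name)))
  m <- if (correct_all_nodes) length(nodes) else length(pool)
  # vectorized neighborhoods for the whole pool
  nbs <- igraph::ego(net, order = depth, nodes = pool, mindist = 1L)
  set_n <- length(members)
  N_all <- length(nodes)
  res <- data.frame(gene = pool,
                    neighborhood_size = NA_integer_,
                    overlap_count = NA_integer_,
                    kd_p = NA_real_, stringsAsFactors = FALSE)
  member_set <- members
  for (i in seq_along(pool)) {
    nbhd <- setdiff(nbs[[i]]$name, pool[[i]])
    k <- length(intersect(nbhd, member_set))
    K <- set_n - (pool[[i]] %in% member_set)   # set size within the universe
    res$neighborhood_size[i] <- length(nbhd)
    res$overlap_count[i] <- k
    res$kd_p[i] <- hyper_p(k, length(nbhd), K, N_all - 1L)
  }
  res$kd_p_corrected <- pmin(1, res$kd_p * m)
  res$significant <- res$kd_p_corrected < alpha
  res <- res[order(res$kd_p, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_candidates") <- m
  res
}

#' Replication of key drivers in an independent network
#'
#' A key driver from network A replicates when it is present in network B
#' and Bonferroni-significant there for the same gene set. The replication
#' fraction is replicated / testable, where testable KDs are those present
#' in B.
#'
#' @param kds character vector of KD gene names found in network A.
#' @param net_b igraph replication network.
#' @param gene_set the same gene set used in network A.
#' @param alpha,depth as in [kd_scan()].
#' @return list with `fraction`, `n_testable`, and per-KD data.frame `flags`.
#' @export
replicate_kds <- function(kds, net_b, gene_set, alpha = 0.05, depth = 3L) {
  scan_b <- kd_scan(net_b, gene_set, alpha = alpha, depth = depth)
  present <- kds %in% igraph::V(net_b)$name
  sig_b <- if (nrow(scan_b)) scan_b$gene[scan_b$significant] else character()
  replicated <- kds %in% sig_b
  flags <- data.frame(gene = kds, present_in_b = present,
                      replicated = replicated, stringsAsFactors = FALSE)
  n_testable <- sum(present)
  list(fraction = if (n_testable) sum(replicated) / n_testable else NA_real_,
       n_testable = n_testable, flags = flags)
}

#' Tiered ranking of key drivers by orthogonal evidence
#'
#' Tier `GWAS`: KDs one of whose own eSNPs reaches GWAS p < `g_thresh`
#' (sorted by that minimum p). Tier `TWAS`: remaining KDs whose expression
#' is transcriptome-wide Bonferroni-significant for a trait (sorted by that
#' p). Tier `MULTI`: remaining KDs significant in two or more networks
#' (sorted by kd_p). Everything else is `OTHER`, sorted by kd_p. The global
#' rank is tier order then within-tier order.
#'
#' @param kds data.frame with at least `gene` and `kd_p` (e.g. significant
#'   rows of [kd_scan()]); an optional `network` column feeds the MULTI
#'   tier.
#' @param esnp eSNP table (gene -> SNPs).
#' @param gwas GWAS table with `p_<trait>` columns.
#' @param twas trait-association table from [associate_traits()].
#' @param g_thresh GWAS tier threshold (default 1e-5).
#' @param t_alpha family alpha for the TWAS tier (default 0.05, applied as
#'   the Bonferroni flag already present in `twas`).
#' @return `kds` with `min_esnp_gwas_p`, `twas_p`, `tier`, `rank` columns,
#'   sorted by rank.
#' @export
rank_kds <- function(kds, esnp, gwas, twas, g_thresh = 1e-5, t_alpha = 0.05) {
  if (!nrow(kds)) return(cbind(kds, tier = character(), rank = integer()))
  pcols <- grep("^p_", colnames(gwas), value = TRUE)
  min_gwas <- vapply(kds$gene, function(g) {
    snps <- unique(esnp$snp_id[esnp$gene_id == g])
    rows <- gwas[gwas$snp_id %in% snps, pcols, drop = FALSE]
    if (!nrow(rows)) NA_real_ else min(as.matrix(rows))
  }, 1)
  twas_sig <- twas[twas$bonferroni_significant, , drop = FALSE]
  twas_p <- vapply(kds$gene, function(g) {
    rows <- twas_sig[twas_sig$gene_id == g, , drop = FALSE]
    if (!nrow(rows)) NA_real_ else min(rows$p)
  }, 1)
  multi <- if ("network" %in% colnames(kds)) {
    counts <- tapply(kds$network, kds$gene, function(x) length(unique(x)))
    counts[kds$gene] >= 2L
  } else rep(FALSE, nrow(kds))

  kds$min_esnp_gwas_p <- min_gwas
  kds$twas_p <- twas_p
  kds$tier <- "OTHER"
  kds$tier[multi] <- "MULTI"
  kds$tier[!is.na(twas_p)] <- "TWAS"
  kds$tier[!is.na(min_gwas) & min_gwas < g_thresh] <- "GWAS"
  tier_order <- c(GWAS = 1L, TWAS = 2L, MULTI = 3L, OTHER = 4L)
  within <- ifelse(kds$tier == "GWAS", kds$min_esnp_gwas_p,
                   ifelse(kds$tier == "TWAS", kds$twas_p, kds$kd_p))
  ord <- order(tier_order[kds$tier], within, kds$gene)
  kds <- kds[ord, , drop = FALSE]
  kds$rank <- seq_len(nrow(kds))
  rownames(kds) <- NULL
  kds
}
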