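# Key-driver-centered subnetworks and their enrichment against literature
# gene lists, flat annotation terms, and cross-species knockout signatures.

#' Genetic subnetwork of a SNP
#'
#' Star graph linking one SNP to every gene whose expression it associates
#' with in the eSNP table, edges labeled cis/trans, nodes annotated by
#' membership in supplied candidate gene sets.
#'
#' @param snp_id SNP identifier.
#' @param esnp eSNP table.
#' @param candidate_sets named list of gene sets used for node role labels
#'   (role `"both"` when a gene is in several).
#' @return list with `center`, `nodes` (data.frame gene, kind, role),
#'   `edges` (data.frame from, to, kind).
#' @export
genetic_subnetwork <- function(snp_id, esnp, candidate_sets = list()) {
  rows <- esnp[esnp$snp_id == snp_id, , drop = FALSE]
  if (!nrow(rows)) nd_stop(paste("SNP absent from eSNP table:", snp_id))
  role <- vapply(rows$gene_id, function(g) {
    hits <- names(candidate_sets)[vapply(candidate_sets, function(s) g %in% s,
                                         logical(1))]
    if (length(hits) >= 2L) "both" else if (length(hits) == 1L) hits else "other"
  }, "")
  list(center = snp_id, kind = "genetic",
       nodes = data.frame(gene = rows$gene_id, kind = rows$kind, role = role,
                          stringsAsFactors = FALSE, row.names = NULL),
       edges = data.frame(from = snp_id, to = rows$gene_id, kind = rows$kind,
                          stringsAsFactors = FALSE))
}

#' Interaction subnetwork around a key driver
#'
#' Induced subgraph on the key driver plus its <=`depth`-layer neighborhood
#' (same expansion as [kd_neighborhood()]).
#'
#' @param net igraph graph.
#' @param kd center node name.
#' @param depth neighborhood depth (default 3).
#' @return list with `center`, `genes` (center included), and `graph`
#'   (induced igraph subgraph).
#' @export
interaction_subnetwork <- function(net, kd, depth = 3L) {
  nbhd <- kd_neighborhood(net, kd, depth)
  genes <- c(kd, nbhd)
  list(center = kd, kind = "interaction", genes = genes,
       graph = igraph::induced_subgraph(net, genes))
}

#' Hypergeometric enrichment of a query gene set in a reference set
#'
#' k = |query ∩ reference|, n = |query|, K = |reference|, N = |universe|
#' (all after intersection with the explicit universe; genes outside it are
#' dropped with a message). Fold enrichment is (k/n)/(K/N) and the p-value
#' the upper tail P(X >= k). The universe must always be supplied: the
#' appropriate background (e.g. all genes with literature annotation)
#' changes the answer and is never inferred silently.
#'
#' @param query,reference,universe character vectors of gene symbols.
#' @return list k, n, K, N, fold, p.
#' @export
set_enrichment <- function(query, reference, universe) {
  universe <- unique(norm_symbol(universe))
  if (!length(universe)) nd_stop("set_enrichment: empty universe")
  q0 <- unique(norm_symbol(query))
  query <- intersect(q0, universe)
  dropped <- length(q0) - length(query)
  if (dropped) message(sprintf("set_enrichment: %d query gene(s) outside universe dropped", dropped))
  if (!length(query)) nd_stop("set_enrichment: empty query after intersection")
  reference <- intersect(unique(norm_symbol(reference)), universe)
  k <- length(intersect(query, reference))
  n <- length(query); K <- length(reference); N <- length(universe)
  list(k = k, n = n, K = K, N = N,
       fold = fold_enrichment(k, n, K, N), p = hyper_p(k, n, K, N))
}

#' Overlap of a subnetwork with a cross-species knockout DE signature
#'
#' Mouse DE calls (q < `q_max`) are mapped to human symbols through the
#' ortholog table and tested for enrichment in the subnetwork's genes by
#' [set_enrichment()] over the supplied universe.
#'
#' @param subnet_genes character vector (e.g. `interaction_subnetwork()$genes`
#'   or genetic subnetwork node genes).
#' @param mouse_de mouse DE table (see [read_mouse_de()]).
#' @param orthologs named vector mouse id -> human symbol.
#' @param universe explicit gene universe.
#' @param q_max DE call threshold (default 0.05).
#' @return [set_enrichment()] result plus `n_de_mapped`.
#' @export
mouse_overlap <- function(subnet_genes, mouse_de, orthologs, universe,
                          q_max = 0.05) {
  de_mouse <- mouse_de$mouse_gene_id[mouse_de$q_value < q_max]
  de_human <- unname(orthologs[intersect(de_mouse, names(orthologs))])
  de_human <- de_human[!is.na(de_human)]
  if (!length(de_human)) nd_stop("mouse_overlap: no mappable DE genes")
  res <- set_enrichment(subnet_genes, de_human, universe)
  res$n_de_mapped <- length(unique(de_human))
  res
}

#' Annotation-term enrichment of a gene set
#'
#' Per term, a one-sided Fisher (hypergeometric) test of the query against
#' the term's genes over the universe, Bonferroni-corrected by the number
#' of terms in the table; the per-term significance threshold is
#' `family_alpha / n_terms`.
#'
#' @param query character vector of gene symbols.
#' @param annotations named list term -> genes (see [read_annotations()]).
#' @param universe explicit gene universe.
#' @param family_alpha family-wise alpha (default 0.05).
#' @return data.frame term, k, n, K, N, fold, p, p_bonf, significant,
#'   sorted by p; attribute `"threshold"` = family_alpha / n_terms.
#' @export
annotation_enrichment <- function(query, annotations, universe,
                                  family_alpha = 0.05) {
  stopifnot(is.list(annotations), length(annotations) >= 1L)
  universe <- unique(norm_symbol(universe))
  query <- intersect(unique(norm_symbol(query)), universe)
  if (!length(query)) nd_stop("annotation_enrichment: empty query after intersection")
  n_terms <- length(annotations)
  thr <- family_alpha / n_terms
  rows <- lapply(names(annotations), function(tm) {
    ref <- intersect(unique(norm_symbol(annotations[[tm]])), universe)
    k <- length(intersect(query, ref))
    data.frame(term = tm, k = k, n = length(query), K = length(ref),
               N = length(universe),
               fold = fold_enrichment(k, length(query), length(ref),
                                      length(universe)),
               p = hyper_p(k, length(query), length(ref), length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonf <- pmin(1, out$p * n_terms)
  out$significant <- out$p < thr
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}
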