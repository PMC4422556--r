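# Readers and writers for the plain-text formats the pipeline exchanges:
# TSV tables (expression, phenotypes, eSNPs, GWAS, annotations, mouse DE,
# orthologs), GMT gene-set collections, and edge-list networks. All loaders
# validate strictly and fail with a classed "netdriver_format_error".

fmt_stop <- function(msg) nd_stop(msg, class = "netdriver_format_error")

norm_symbol <- function(x) toupper(trimws(x))

# ---- expression ------------------------------------------------------------

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene identifiers, header row holds sample identifiers,
#' cells are log-scale expression values.
#'
#' @param path TSV file path.
#' @param missing_policy `"reject"` (default) fails on any missing value;
#'   `"drop_gene"` silently drops genes with missing cells.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path, missing_policy = c("reject", "drop_gene")) {
  missing_policy <- match.arg(missing_policy)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) fmt_stop("expression file needs a gene column plus >=1 sample column")
  genes <- norm_symbol(df[[1L]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) fmt_stop(paste0("duplicated gene id(s): ", paste(unique(dup), collapse = ", ")))
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) fmt_stop("duplicated sample ids in header")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) fmt_stop("non-numeric expression cell encountered")
  rownames(vals) <- genes
  if (anyNA(vals)) {
    if (missing_policy == "reject") fmt_stop("missing expression values (policy: reject)")
    keep <- rowSums(is.na(vals)) == 0L
    vals <- vals[keep, , drop = FALSE]
  }
  message(sprintf("read_expression: %d genes x %d samples", nrow(vals), ncol(vals)))
  vals
}

#' Write an expression matrix as TSV
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- phenotypes ------------------------------------------------------------

#' Read a sample phenotype/covariate table
#'
#' Expects at least `sample_id`, `sbp`, `dbp` columns; `htn` is derived from
#' the clinical rule SBP >= 140 mm Hg or DBP >= 90 mm Hg when absent, and
#' checked against it when present. Columns whose names start with `cell_`
#' are treated as cell-type proportions and must lie in [0, 1].
#'
#' @param path TSV path.
#' @return data.frame, one row per sample.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", "sbp", "dbp")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) fmt_stop(paste("phenotype table missing column(s):",
                                   paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) fmt_stop("duplicated sample_id in phenotype table")
  derived <- as.integer(df$sbp >= 140 | df$dbp >= 90)
  if (!"htn" %in% colnames(df)) {
    df$htn <- derived
  } else if (!all(df$htn == derived)) {
    fmt_stop("htn flag inconsistent with SBP >= 140 / DBP >= 90 rule")
  }
  cells <- grep("^cell_", colnames(df), value = TRUE)
  for (cc in cells) {
    if (any(df[[cc]] < 0 | df[[cc]] > 1)) fmt_stop(paste("cell proportion outside [0,1]:", cc))
  }
  df
}

#' @rdname read_phenotypes
#' @param phen phenotype data.frame.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GMT gene sets ---------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT path.
#' @return named list of character vectors (unique, uppercased members);
#'   descriptions kept in attribute `"descriptions"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) fmt_stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- f[[1L]]
    if (nm %in% names(sets)) fmt_stop(paste("duplicated gene-set name:", nm))
    members <- unique(norm_symbol(f[-(1:2)]))
    members <- members[nzchar(members)]
    if (!length(members)) fmt_stop(sprintf("GMT line %d (%s) has no members", i, nm))
    sets[[nm]] <- members
    desc[[nm]] <- f[[2L]]
  }
  attr(sets, "descriptions") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- attr(sets, "descriptions")
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(sets)) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    writeLines(paste(c(nm, d, sets[[nm]]), collapse = "\t"), con)
  }
  invisible(path)
}

# ---- networks --------------------------------------------------------------

#' Read a molecular network from a two-column edge list
#'
#' Extra columns (e.g. weights) are ignored. Self-loops are dropped with a
#' message; duplicate edges (including reversed duplicates when undirected)
#' are collapsed.
#'
#' @param path edge-list TSV (no header by default; a header line whose first
#'   field is `source` or `from` is skipped).
#' @param directed logical.
#' @param name provenance label stored as a graph attribute.
#' @return an [igraph::graph] object.
#' @export
read_network <- function(path, directed = FALSE, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^(source|from)\t", tolower(lines[[1L]]))) {
    lines <- lines[-1L]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) fmt_stop(sprintf("unreadable edge at line %d", bad[[1L]]))
  src <- norm_symbol(vapply(parts, `[[`, "", 1L))
  dst <- norm_symbol(vapply(parts, `[[`, "", 2L))
  loops <- src == dst
  g <- igraph::graph_from_data_frame(
    data.frame(from = src[!loops], to = dst[!loops], stringsAsFactors = FALSE),
    directed = directed,
    vertices = data.frame(name = unique(c(src, dst)), stringsAsFactors = FALSE)
  )
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (any(loops)) message(sprintf("read_network: dropped %d self-loop(s)", sum(loops)))
  igraph::graph_attr(g, "name") <- name
  g
}

#' @rdname read_network
#' @param g igraph graph.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- eSNPs / GWAS / LD -----------------------------------------------------

#' Read an eSNP (eQTL) table
#'
#' Columns: `snp_id`, `gene_id`, `kind` (cis/trans), `eqtl_p`, `eqtl_fdr`.
#'
#' @param path TSV path.
#' @param fdr_max keep records with `eqtl_fdr < fdr_max` (default 0.1, the
#'   conventional discovery threshold for blood eQTL panels); `NULL` keeps all.
#' @return data.frame of unique (snp_id, gene_id) records.
#' @export
read_esnp <- function(path, fdr_max = 0.1) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "kind", "eqtl_p", "eqtl_fdr")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) fmt_stop(paste("eSNP table missing column(s):", paste(miss, collapse = ", ")))
  if (!all(df$kind %in% c("cis", "trans"))) fmt_stop("eSNP kind must be cis or trans")
  if (any(df$eqtl_p <= 0 | df$eqtl_p > 1)) fmt_stop("eqtl_p outside (0,1]")
  df$gene_id <- norm_symbol(df$gene_id)
  if (anyDuplicated(df[, c("snp_id", "gene_id")])) fmt_stop("duplicated (snp_id, gene_id) pair")
  if (!is.null(fdr_max)) df <- df[df$eqtl_fdr < fdr_max, , drop = FALSE]
  df
}

#' Read GWAS summary statistics
#'
#' Columns: `snp_id`, `chr`, `pos`, then one `p_<trait>` column per trait
#' (e.g. `p_sbp`, `p_dbp`), p-values in (0,1].
#'
#' @param path TSV path.
#' @return data.frame keyed by unique `snp_id`.
#' @export
read_gwas <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_id", "chr", "pos")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) fmt_stop(paste("GWAS table missing column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$snp_id)) fmt_stop("duplicated snp_id in GWAS table")
  pcols <- grep("^p_", colnames(df), value = TRUE)
  if (!length(pcols)) fmt_stop("GWAS table has no p_<trait> column")
  for (pc in pcols) {
    if (any(df[[pc]] <= 0 | df[[pc]] > 1)) fmt_stop(paste("p-values outside (0,1] in", pc))
  }
  df
}

#' Pairwise LD r-squared from a dosage matrix
#'
#' r2 is the squared Pearson correlation of allele dosages, the standard
#' summary used when pruning SNPs at r2 >= 0.8. Constant dosage columns have
#' undefined correlation; their pairs are recorded as 0 with a warning.
#'
#' @param dosages samples x SNPs numeric matrix (dosages in [0, 2]), SNP ids
#'   as column names.
#' @return symmetric SNPs x SNPs matrix with unit diagonal.
#' @export
compute_ld <- function(dosages) {
  stopifnot(is.matrix(dosages), nrow(dosages) >= 2L)
  if (is.null(colnames(dosages))) fmt_stop("dosage matrix needs SNP ids as column names")
  sds <- apply(dosages, 2L, stats::sd)
  const <- sds == 0
  if (any(const)) warning(sprintf("compute_ld: %d constant SNP column(s); their r2 set to 0", sum(const)))
  r <- suppressWarnings(stats::cor(dosages))
  r2 <- r^2
  r2[is.na(r2)] <- 0
  diag(r2) <- 1
  r2
}

#' Read a pairwise LD table into an r-squared matrix
#'
#' @param path TSV with columns `snp_a`, `snp_b`, `r2`.
#' @param snp_ids optional full SNP universe; pairs absent from the file are
#'   treated as unlinked (r2 = 0).
#' @return symmetric r2 matrix with unit diagonal.
#' @export
read_ld <- function(path, snp_ids = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (length(setdiff(need, colnames(df)))) fmt_stop("LD table needs snp_a, snp_b, r2 columns")
  if (any(df$r2 < 0 | df$r2 > 1)) fmt_stop("r2 outside [0,1]")
  ids <- if (is.null(snp_ids)) unique(c(df$snp_a, df$snp_b)) else snp_ids
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  ia <- match(df$snp_a, ids); ib <- match(df$snp_b, ids)
  ok <- !is.na(ia) & !is.na(ib)
  m[cbind(ia[ok], ib[ok])] <- df$r2[ok]
  m[cbind(ib[ok], ia[ok])] <- df$r2[ok]
  m
}

# ---- annotations / orthologs / mouse DE ------------------------------------

#' Read a GO-style term annotation table
#'
#' @param path TSV with columns `term_id`, `gene_id`; one row per
#'   term-gene link.
#' @return named list term_id -> character vector of genes.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (length(setdiff(c("term_id", "gene_id"), colnames(df))))
    fmt_stop("annotation table needs term_id, gene_id columns")
  df$gene_id <- norm_symbol(df$gene_id)
  out <- split(df$gene_id, df$term_id)
  out <- lapply(out, unique)
  if (any(!lengths(out))) fmt_stop("annotation term with no genes")
  out
}

#' Read a two-column human-mouse ortholog map
#'
#' @param path TSV with columns `mouse_gene_id`, `human_gene_id`.
#' @return named character vector: mouse id -> human symbol.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (length(setdiff(c("mouse_gene_id", "human_gene_id"), colnames(df))))
    fmt_stop("ortholog map needs mouse_gene_id, human_gene_id columns")
  if (anyDuplicated(df$mouse_gene_id)) fmt_stop("ortholog map is not 1:1 on mouse ids")
  stats::setNames(norm_symbol(df$human_gene_id), df$mouse_gene_id)
}

#' Read a mouse differential-expression table
#'
#' @param path TSV with columns `mouse_gene_id`, `q_value` (and optionally
#'   `direction`).
#' @return data.frame with unique gene ids, q in [0,1].
#' @export
read_mouse_de <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (length(setdiff(c("mouse_gene_id", "q_value"), colnames(df))))
    fmt_stop("mouse DE table needs mouse_gene_id, q_value columns")
  if (anyDuplicated(df$mouse_gene_id)) fmt_stop("duplicated mouse gene id")
  if (any(df$q_value < 0 | df$q_value > 1)) fmt_stop("q_value outside [0,1]")
  df
}

#' Generic TSV writer used by every stage output
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
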