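# Single-gene trait association and the Bonferroni signature gene set.

#' Associate each gene's residual expression with blood-pressure traits
#'
#' Per gene x trait, a simple linear regression of the trait on residual
#' expression — equivalently a Pearson correlation with a two-sided t-test.
#' The binary hypertension flag is handled by the same linear score test,
#' keeping one testing framework across the continuous and binary traits
#' (logistic regression is available via `htn_logistic = TRUE`).
#'
#' @param resid genes x samples residual matrix.
#' @param phen phenotype data.frame with `sample_id` and trait columns.
#' @param traits character subset of `c("sbp", "dbp", "htn")`.
#' @param htn_logistic use logistic regression for `htn` instead of the
#'   linear score test.
#' @return data.frame with gene_id, trait, beta, r, p, bonferroni_significant
#'   (family alpha 0.05 over genes, per trait).
#' @export
associate_traits <- function(resid, phen, traits = c("sbp", "dbp", "htn"),
                             htn_logistic = FALSE) {
  if (ncol(resid) < 4L) nd_stop("associate_traits needs >= 4 samples")
  if (!setequal(colnames(resid), phen$sample_id))
    nd_stop("sample mismatch between expression and phenotype table")
  phen <- phen[match(colnames(resid), phen$sample_id), , drop = FALSE]
  miss <- setdiff(traits, colnames(phen))
  if (length(miss)) nd_stop(paste("trait(s) missing:", paste(miss, collapse = ", ")))
  n <- ncol(resid)
  G <- nrow(resid)
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    trait <- traits[[ti]]
    y <- as.numeric(phen[[trait]])
    if (stats::sd(y) == 0) nd_stop(paste("constant trait:", trait))
    if (trait == "htn" && htn_logistic) {
      res <- t(apply(resid, 1L, function(x) {
        fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
        cf <- summary(fit)$coefficients
        c(cf["x", "Estimate"], cf["x", "Pr(>|z|)"])
      }))
      r <- suppressWarnings(as.numeric(stats::cor(t(resid), y)))
      beta <- res[, 1L]; p <- res[, 2L]
    } else {
      sx <- apply(resid, 1L, stats::sd)
      r <- suppressWarnings(as.numeric(stats::cor(t(resid), y)))
      r[is.na(r)] <- 0
      beta <- r * stats::sd(y) / ifelse(sx > 0, sx, Inf)
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    out[[ti]] <- data.frame(
      gene_id = rownames(resid), trait = toupper(trait),
      beta = beta, r = r, p = p,
      bonferroni_significant = p < 0.05 / G,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  do.call(rbind, out)
}

#' Build the trait signature gene set from the association table
#'
#' The signature is the union of Bonferroni-significant genes across traits,
#' with per-trait counts, the genes significant for every tested trait, and
#' a positive/negative direction tally (direction = sign of the correlation
#' for the trait of a gene's smallest p).
#'
#' @param assoc output of [associate_traits()].
#' @param alpha family-wise alpha (must match the Bonferroni flags; default
#'   0.05).
#' @return list with `genes` (character vector, possibly empty),
#'   `per_trait_counts`, `all_traits_genes`, `n_positive`, `n_negative`.
#' @export
signature_set <- function(assoc, alpha = 0.05) {
  sig <- assoc[assoc$bonferroni_significant, , drop = FALSE]
  genes <- sort(unique(sig$gene_id))
  per_trait <- vapply(split(sig$gene_id, sig$trait), function(g) length(unique(g)), 1L)
  traits <- unique(assoc$trait)
  all_three <- genes[vapply(genes, function(g)
    all(traits %in% sig$trait[sig$gene_id == g]), logical(1))]
  direction <- vapply(genes, function(g) {
    rows <- sig[sig$gene_id == g, , drop = FALSE]
    sign(rows$r[which.min(rows$p)])
  }, numeric(1))
  list(genes = genes,
       per_trait_counts = per_trait,
       all_traits_genes = all_three,
       n_positive = sum(direction > 0),
       n_negative = sum(direction < 0))
}
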