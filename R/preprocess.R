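# Covariate residualization and the cell-type association scan.

# Build a full-rank design matrix from phenotype columns; categorical
# covariates are expanded to indicators, collinear columns dropped with a
# message. An intercept is always included.
build_design <- function(phen, covariates) {
  miss <- setdiff(covariates, colnames(phen))
  if (length(miss))
    nd_stop(paste("unknown covariate(s):", paste(miss, collapse = ", ")))
  X <- matrix(1, nrow(phen), 1L, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    v <- phen[[cv]]
    if (is.numeric(v)) {
      X <- cbind(X, stats::setNames(data.frame(v), cv))
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) next
      ind <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(ind) <- paste0(cv, levels(f)[-1L])
      X <- cbind(X, ind)
    }
  }
  X <- as.matrix(X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    message("build_design: dropping collinear column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  X
}

#' Residualize expression on phenotype covariates
#'
#' Per-gene ordinary least-squares residuals on the stated covariate design
#' (intercept always included; categorical covariates expanded to
#' indicators; collinear columns dropped). The pipeline residualizes on
#' age, sex, BMI, cell proportions, and cohort before network construction,
#' mirroring the standard pre-adjustment of blood expression for trait
#' covariates. Samples are matched by ID between the matrix columns and the
#' phenotype table.
#'
#' @param expr genes x samples matrix.
#' @param phen phenotype data.frame with `sample_id`.
#' @param covariates character vector of phenotype column names (empty for
#'   intercept-only centering).
#' @return matrix of residuals, same shape and dimnames as `expr`.
#' @export
residualize <- function(expr, phen, covariates = character()) {
  if (!setequal(colnames(expr), phen$sample_id))
    nd_stop("sample mismatch between expression and phenotype table")
  phen <- phen[match(colnames(expr), phen$sample_id), , drop = FALSE]
  X <- build_design(phen, covariates)
  Q <- qr.Q(qr(X))
  # residual of each gene (rows): E - (E Q) Q'
  res <- expr - (expr %*% Q) %*% t(Q)
  dimnames(res) <- dimnames(expr)
  res
}

#' Scan genes for association with cell-type proportions
#'
#' Per gene, an F-test of the joint regression on the named cell-proportion
#' columns (against the intercept-only null), Bonferroni-corrected across
#' genes. Whole-blood expression is strongly driven by cell composition;
#' this scan quantifies how much, and motivates running the pipeline in
#' both cell-adjusted and unadjusted tracks.
#'
#' @param expr genes x samples matrix (raw or technically residualized).
#' @param phen phenotype data.frame.
#' @param cell_prop_names columns of `phen` holding proportions; default all
#'   columns starting `cell_`.
#' @param alpha family-wise error target (default 0.05).
#' @return list with `table` (gene, f, p, significant) and
#'   `fraction_significant`.
#' @export
cell_type_scan <- function(expr, phen,
                           cell_prop_names = grep("^cell_", colnames(phen),
                                                  value = TRUE),
                           alpha = 0.05) {
  if (ncol(expr) < 3L) nd_stop("cell_type_scan needs >= 3 samples")
  if (!setequal(colnames(expr), phen$sample_id))
    nd_stop("sample mismatch between expression and phenotype table")
  phen <- phen[match(colnames(expr), phen$sample_id), , drop = FALSE]
  X <- build_design(phen, cell_prop_names)
  q <- ncol(X) - 1L
  n <- ncol(expr)
  df2 <- n - ncol(X)
  if (q < 1L || df2 < 1L) nd_stop("degenerate cell-proportion design")
  Q <- qr.Q(qr(X))
  center <- expr - rowMeans(expr)
  rss0 <- rowSums(center^2)
  resid1 <- expr - (expr %*% Q) %*% t(Q)
  rss1 <- rowSums(resid1^2)
  constant <- rss0 <= .Machine$double.eps * n
  f <- ((rss0 - rss1) / q) / (rss1 / df2)
  p <- stats::pf(f, q, df2, lower.tail = FALSE)
  if (any(constant)) {
    warning(sprintf("cell_type_scan: %d constant gene(s), p set to 1",
                    sum(constant)))
    p[constant] <- 1
    f[constant] <- 0
  }
  thr <- alpha / nrow(expr)
  tab <- data.frame(gene_id = rownames(expr), f = f, p = p,
                    significant = p < thr, stringsAsFactors = FALSE,
                    row.names = NULL)
  list(table = tab, fraction_significant = mean(tab$significant),
       bonferroni_threshold = thr)
}
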