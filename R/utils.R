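# Internal helpers shared across the pipeline.

#' Derive a reproducible sub-stream seed for a named pipeline stage
#'
#' A single user-supplied seed is expanded into independent per-stage seeds
#' so that each simulation or permutation stage can be regenerated on its
#' own without replaying the stages before it. The expansion is a small
#' deterministic hash of the stage name folded into the base seed; it stays
#' within the 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed integer base seed.
#' @param stage character stage label (e.g. `"expression"`, `"network"`).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483629)
}

# Module colour vocabulary, assigned to detected modules by decreasing size.
# The names themselves carry no meaning; "grey" is reserved for unassigned
# genes.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue", "darkred",
  "darkgreen", "darkturquoise", "darkgrey", "orange", "darkorange", "white",
  "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
  "darkolivegreen", "darkmagenta", "chocolate", "sienna", "plum", "thistle",
  "maroon", "navy"
)

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Shared by every enrichment test in the pipeline: the probability of
#' observing `k` or more reference genes in a draw of `n` from a universe of
#' `N` containing `K` reference genes. Identical to the one-sided (greater)
#' Fisher exact p-value for the corresponding 2x2 table.
#'
#' @param k overlap count.
#' @param n query (draw) size.
#' @param K reference set size in the universe.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hyper_p <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 1, k <= n, K <= N, n <= N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment (k/n) / (K/N)
#'
#' @inheritParams hyper_p
#' @return non-negative real; 1 means no enrichment.
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (n == 0 || K == 0) return(NA_real_)
  (k / n) / (K / N)
}

# Benjamini-Hochberg step-up, thin wrapper kept for a single obvious call
# site; uses stats::p.adjust.
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

# Adjusted Rand index between two labelings (used by recovery tests and the
# pipeline's truth-matching report).
#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return ARI in [-1, 1]; 1 for identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxindex <- (si + sj) / 2
  if (maxindex == expected) return(1)
  (sij - expected) / (maxindex - expected)
}

# Safe sampling from a vector of ids: never falls into sample()'s
# scalar-means-1:n behavior when the vector has length 1.
resample <- function(x, size = length(x)) x[sample.int(length(x), size)]

# Internal: stop with a classed error so tests can assert on error types.
nd_stop <- function(msg, class = "netdriver_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fmt_perm_p <- function(count, n_perm) {
  ifelse(count == 0, "<0.001", formatC(count / n_perm, format = "g"))
}
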