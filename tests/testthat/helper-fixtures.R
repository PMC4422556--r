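# Shared fixtures, all built in code.

tiny_expr <- function(genes = 3, samples = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(genes * samples), 4), genes, samples,
              dimnames = list(sprintf("G%02d", seq_len(genes)),
                              sprintf("S%02d", seq_len(samples))))
  m
}

# phenotype table with n samples matching an expression matrix's columns
tiny_phen <- function(samples, seed = 1) {
  set.seed(seed)
  n <- length(samples)
  cells <- matrix(rgamma(3 * n, 5), n, 3)
  cells <- cells / rowSums(cells)
  sbp <- rnorm(n, 120, 15); dbp <- rnorm(n, 80, 10)
  data.frame(sample_id = samples, sbp = sbp, dbp = dbp,
             htn = as.integer(sbp >= 140 | dbp >= 90),
             age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
             bmi = rnorm(n, 27, 4),
             cell_a = cells[, 1], cell_b = cells[, 2], cell_c = cells[, 3],
             cohort = sample(c("x", "y"), n, TRUE),
             stringsAsFactors = FALSE)
}

# undirected igraph path A-B-C-D-E...
path_graph <- function(n = 5) {
  nm <- LETTERS[seq_len(n)]
  igraph::make_graph(edges = as.vector(rbind(nm[-n], nm[-1])), directed = FALSE)
}

star_graph <- function(hub = "HUB", leaves = sprintf("L%02d", 1:10)) {
  igraph::make_graph(edges = as.vector(rbind(hub, leaves)), directed = FALSE)
}

# brute-force TOM oracle: triple loop over the formula
tom_oracle <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - 1
  w <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    w[i, j] <- (l + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(w) <- dimnames(A)
  w
}

# exhaustive hypergeometric tail: enumerate all C(N, n) draws
enum_hyper_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  ref <- seq_len(K)           # first K elements are the reference set
  hits <- colSums(matrix(draws %in% ref, nrow = n))
  mean(hits >= k)
}
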