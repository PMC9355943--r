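# Small fixture builders shared across the suite.

# random sparse counts ExpressionMatrix
random_counts <- function(n_genes = 20, n_obs = 15, density = 0.3,
                          seed = 1, gene_prefix = "G") {
  set.seed(seed)
  v <- matrix(0L, n_genes, n_obs)
  nz <- rbinom(n_genes * n_obs, 1, density) == 1
  v[nz] <- rpois(sum(nz), 5) + 1L
  expression_matrix(v, sprintf("%s%03d", gene_prefix, seq_len(n_genes)),
                    sprintf("C%03d", seq_len(n_obs)), layer = "counts")
}

# a scaled-layer matrix with two well-separated blobs of cells
two_blob_matrix <- function(n_genes = 40, n_per_blob = 60, sep = 6,
                            noise = 0.5, seed = 1) {
  set.seed(seed)
  mu <- cbind(rep(sep, n_genes) * rep(c(1, -1), length.out = n_genes),
              rep(-sep, n_genes) * rep(c(1, -1), length.out = n_genes))
  v <- cbind(mu[, 1] + matrix(rnorm(n_genes * n_per_blob, 0, noise),
                              n_genes),
             mu[, 2] + matrix(rnorm(n_genes * n_per_blob, 0, noise),
                              n_genes))
  m <- expression_matrix(v, sprintf("G%03d", seq_len(n_genes)),
                         sprintf("C%03d", seq_len(2 * n_per_blob)),
                         layer = "scaled")
  list(m = m, truth = rep(c(1, 2), each = n_per_blob))
}

# random valid adjacency (zero diagonal, entries in [0,1])
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}

# O(n^3) brute-force topological overlap oracle
tom_bruteforce <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- 0
    for (u in seq_len(n)) if (u != i && u != j)
      shared <- shared + a[i, u] * a[u, j]
    tom[i, j] <- (shared + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Benjamini-Hochberg step-up oracle, written independently of p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# exact hypergeometric upper tail from binomial coefficients
hyper_upper_oracle <- function(k, N, K, n) {
  if (k == 0) return(1)
  jmax <- min(K, n)
  sum(choose(K, k:jmax) * choose(N - K, n - (k:jmax))) / choose(N, n)
}
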