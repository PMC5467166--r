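# independent oracles used across tests; deliberately naive implementations

# triple-loop topological overlap
oracle_tom <- function(A) {
  n <- nrow(A)
  k <- rowSums(A) - diag(A)
  W <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l_ij <- 0
    for (u in seq_len(n)) if (u != i && u != j) l_ij <- l_ij + A[i, u] * A[u, j]
    W[i, j] <- (l_ij + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  dimnames(W) <- dimnames(A)
  W
}

# one-sided hypergeometric upper tail P[X >= a] from first principles
oracle_hyper_p <- function(a, set_size, target_size, N) {
  xs <- a:min(set_size, target_size)
  sum(choose(target_size, xs) * choose(N - target_size, set_size - xs)) /
    choose(N, set_size)
}

# brute-force Benjamini-Hochberg: q_i = min over p_(j) * m / j for j >= rank(i)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord]
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  q
}

# brute-force two-sample KS statistic: max |ECDF difference| at all data points
oracle_ks <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}

# random symmetric adjacency with unit diagonal
random_adjacency <- function(n) {
  M <- matrix(stats::runif(n * n), n, n)
  A <- (M + t(M)) / 2
  diag(A) <- 1
  dimnames(A) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  A
}

# exact two-block dissimilarity matrix
block_dissimilarity <- function(sizes) {
  lab <- rep(seq_along(sizes), sizes)
  D <- 1 - outer(lab, lab, "==")
  diag(D) <- 0
  n <- length(lab)
  dimnames(D) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  storage.mode(D) <- "double"
  list(D = D, labels = stats::setNames(lab, rownames(D)))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny deterministic signature
toy_signature <- function(genes, log2fc, p) {
  out <- data.frame(gene_id = genes, log2fc = log2fc, p_value = p,
                    direction = sign(log2fc))
  class(out) <- c("differential_signature", class(out))
  out
}
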