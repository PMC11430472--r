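# Brute-force reference implementations for graph metrics, kept deliberately
# naive and independent of the package's code paths.

# All-pairs shortest paths by Floyd-Warshall on a 0/1 adjacency matrix.
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A != 0] <- 1
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# Global efficiency: mean inverse geodesic over unordered pairs.
bf_efficiency <- function(A) {
  D <- bf_distances(A)
  iv <- 1 / D[upper.tri(D)]
  iv[!is.finite(iv)] <- 0
  mean(iv)
}

# Node-level binary clustering coefficient by neighbour-pair counting.
bf_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (A[nb[a], nb[b]] != 0) links <- links + 1
    2 * links / (k * (k - 1))
  })
}

# Participation coefficient from an explicit community labelling.
bf_participation <- function(A, labels) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    k <- sum(A[i, ])
    if (k == 0) return(0)
    1 - sum(sapply(unique(labels), function(s)
      (sum(A[i, labels == s]) / k)^2))
  })
}

# Best modularity over all 2^n bipartitions (plus the trivial single
# community), by exhaustive search.
bf_best_bipartition_q <- function(A, gamma = 1) {
  n <- nrow(A)
  best <- modularity_q(A, rep(1L, n), gamma)
  best_labels <- rep(1L, n)
  for (mask in 1:(2^n - 2)) {
    lab <- as.integer(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0) + 1L
    q <- modularity_q(A, lab, gamma)
    if (q > best + 1e-12) {
      best <- q
      best_labels <- lab
    }
  }
  list(q = best, labels = best_labels)
}

# Connectivity test via reachability (matrix powers), independent of igraph.
bf_connected <- function(A) {
  n <- nrow(A)
  R <- A != 0
  diag(R) <- TRUE
  for (i in seq_len(n)) R <- R | (R %*% R) > 0
  all(R)
}

# All labeled graphs on n nodes from an edge-subset bitmask.
graph_from_mask <- function(n, mask) {
  A <- matrix(0L, n, n)
  iu <- which(upper.tri(A), arr.ind = TRUE)
  on <- as.logical(bitwAnd(mask, 2^(seq_len(nrow(iu)) - 1)))
  A[iu[on, , drop = FALSE]] <- 1L
  A + t(A)
}

# Seeded random connected graph on n nodes.
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0L, n, n)
    iu <- which(upper.tri(A), arr.ind = TRUE)
    on <- stats::runif(nrow(iu)) < p
    A[iu[on, , drop = FALSE]] <- 1L
    A <- A + t(A)
    if (sum(A) > 0 && bf_connected(A)) return(A)
  }
}
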