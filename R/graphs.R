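#' Binarize a connectivity matrix at a fixed edge density
#'
#' Keeps the `round(density * P(P-1)/2)` largest off-diagonal values (by
#' signed value; each unordered pair counted once) as edges of an undirected
#' unweighted graph. Ties at the cutoff are broken deterministically by
#' ascending (row, column) index.
#'
#' @param cm A `connectivity_matrix` or square symmetric matrix.
#' @param density Edge density in (0, 1]; the default 0.1 keeps the top 10%
#'   of edges (90% sparsity).
#' @param scope Label recorded on the graph ("whole_brain" or a network).
#' @return An object of class `binary_graph`: list with `adjacency`
#'   (P x P 0/1, zero diagonal), `density`, `scope`.
#' @export
binarize_at_density <- function(cm, density = 0.1, scope = "whole_brain") {
  V <- as_conn_values(cm)
  P <- nrow(V)
  if (length(density) != 1L || density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]")
  n_pairs <- P * (P - 1L) / 2
  k <- round(density * n_pairs)
  if (k < 1L)
    stop("density ", density, " yields 0 edges for ", scope,
         " graph with ", P, " nodes")
  iu <- which(upper.tri(V), arr.ind = TRUE)
  vals <- V[iu]
  ord <- order(-vals, iu[, 1L], iu[, 2L])
  keep <- ord[seq_len(k)]
  A <- matrix(0L, P, P)
  A[iu[keep, , drop = FALSE]] <- 1L
  A <- A + t(A)
  dimnames(A) <- dimnames(V)
  structure(list(adjacency = A, density = density, scope = scope),
            class = "binary_graph")
}

as_adj <- function(g) {
  if (inherits(g, "binary_graph")) g$adjacency
  else if (is.matrix(g)) g
  else stop("expected a `binary_graph` or adjacency matrix")
}

#' Unweighted shortest-path (geodesic) distances
#'
#' Breadth-first geodesic lengths between all node pairs of a binary graph;
#' unreachable pairs are `Inf`.
#'
#' @param g A `binary_graph` or 0/1 adjacency matrix.
#' @return P x P matrix of path lengths (0 on the diagonal).
#' @export
graph_shortest_paths <- function(g) {
  A <- as_adj(g)
  ig <- igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected")
  D <- igraph::distances(ig)
  dimnames(D) <- dimnames(A)
  D
}

# inverse distance with 1/Inf = 0; diagonal left as Inf-free 0 distance -> Inf,
# callers exclude the diagonal.
inverse_distance <- function(D) {
  iD <- 1 / D
  iD[is.infinite(D)] <- 0
  iD
}

#' Modularity of a community assignment
#'
#' Newman's modularity `Q = sum_c (e_cc - gamma * a_c^2)` of a labelling,
#' where `e_cc` is the fraction of edges inside community c and `a_c` the
#' fraction of edge ends attached to it.
#'
#' @param g A `binary_graph` or adjacency matrix (>= 1 edge).
#' @param labels Integer community id per node.
#' @param gamma Resolution parameter (default 1).
#' @return Scalar Q.
#' @export
modularity_q <- function(g, labels, gamma = 1) {
  A <- as_adj(g)
  m2 <- sum(A)
  if (m2 == 0) stop("modularity undefined for an edgeless graph")
  k <- rowSums(A)
  same <- outer(labels, labels, "==")
  sum((A - gamma * (k %o% k) / m2)[same]) / m2
}

# Kernighan-Lin style fine-tuning of a +/-1 split vector s for modularity
# matrix Bg (Newman's fine-tuning stage). Deterministic: ties go to the
# lowest index. Returns the improved s.
kl_refine <- function(Bg, s, max_pass = 50L) {
  n <- length(s)
  for (pass in seq_len(max_pass)) {
    s0 <- s
    q0 <- drop(s %*% Bg %*% s)
    best_q <- q0
    best_s <- s
    moved <- rep(FALSE, n)
    cur_s <- s
    cur_q <- q0
    Bs <- as.vector(Bg %*% cur_s)
    for (step in seq_len(n)) {
      # gain of flipping node i: delta = -4 s_i (Bg s)_i + 4 B_ii
      gains <- -4 * cur_s * Bs + 4 * diag(Bg)
      gains[moved] <- -Inf
      i <- which.max(gains)
      cur_q <- cur_q + gains[i]
      Bs <- Bs - 2 * cur_s[i] * Bg[, i]
      cur_s[i] <- -cur_s[i]
      moved[i] <- TRUE
      if (cur_q > best_q + 1e-12) {
        best_q <- cur_q
        best_s <- cur_s
      }
    }
    s <- best_s
    if (best_q <= q0 + 1e-9 * max(1, abs(q0)) || all(s == s0)) break
  }
  s
}

#' Newman community detection (leading eigenvector, deterministic)
#'
#' Divisive spectral community detection: the graph is repeatedly bisected
#' along the sign of the leading eigenvector of the (generalized) modularity
#' matrix, each split refined by Kernighan-Lin style single-node moves, and
#' a split is accepted only if it increases modularity. Zero eigenvector
#' entries join the nonnegative side; all tie-breaks are by node index, so
#' the algorithm is fully deterministic.
#'
#' @param g A `binary_graph` or adjacency matrix with at least one edge.
#' @param gamma Resolution parameter (default 1).
#' @return An object of class `community_assignment`: list with `labels`
#'   (integer community per node, ids 1..k), `Q` (modularity of the returned
#'   labelling) and `gamma`.
#' @export
newman_modularity <- function(g, gamma = 1) {
  A <- as_adj(g)
  P <- nrow(A)
  m2 <- sum(A)
  if (m2 == 0) stop("community detection undefined for an edgeless graph")
  k <- rowSums(A)
  B <- A - gamma * (k %o% k) / m2
  labels <- rep(NA_integer_, P)
  next_id <- 0L
  stack <- list(seq_len(P))
  while (length(stack)) {
    grp <- stack[[1L]]
    stack <- stack[-1L]
    if (length(grp) == 1L) {
      next_id <- next_id + 1L
      labels[grp] <- next_id
      next
    }
    Bg <- B[grp, grp, drop = FALSE]
    diag(Bg) <- diag(Bg) - rowSums(Bg)
    ev <- eigen((Bg + t(Bg)) / 2, symmetric = TRUE)
    v <- ev$vectors[, 1L]
    if (ev$values[1L] <= 1e-10) {
      next_id <- next_id + 1L
      labels[grp] <- next_id
      next
    }
    s <- ifelse(v >= 0, 1, -1)
    s <- kl_refine(Bg, s)
    dq <- drop(s %*% Bg %*% s) / (2 * m2)
    if (dq <= 1e-10 || all(s == s[1L])) {
      next_id <- next_id + 1L
      labels[grp] <- next_id
      next
    }
    stack <- c(stack, list(grp[s > 0], grp[s < 0]))
  }
  labels <- match(labels, unique(labels))
  structure(list(labels = labels, Q = modularity_q(A, labels, gamma),
                 gamma = gamma),
            class = "community_assignment")
}

#' @export
print.community_assignment <- function(x, ...) {
  cat("Community assignment:", max(x$labels), "communities, Q =",
      format(x$Q, digits = 6), "(gamma =", paste0(x$gamma, ")"), "\n")
  invisible(x)
}

# Node-level binary clustering coefficient: C_i = 2 t_i / (k_i (k_i - 1)),
# 0 for degree < 2.
local_clustering <- function(A) {
  k <- rowSums(A)
  t_i <- diag(A %*% A %*% A) / 2
  C <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  unname(C)
}

# Participation coefficient P_i = 1 - sum_s (k_is / k_i)^2; 0 for degree 0.
participation_coef <- function(A, labels) {
  k <- rowSums(A)
  ks <- rowsum(A, labels)           # communities x nodes (A symmetric)
  p <- 1 - rowSums((t(ks) / ifelse(k == 0, 1, k))^2)
  ifelse(k == 0, 0, p)
}

# All binarized graphs, distances and community structure needed by the
# graph feature block; computed once per connectivity matrix.
graph_struct <- function(cm, partition, density = 0.1) {
  partition <- as_partition(partition)
  V <- as_conn_values(cm)
  if (nrow(V) != partition$parcel_count)
    stop("matrix dimension does not match partition")
  nets <- partition$networks
  wb <- binarize_at_density(V, density, scope = "whole_brain")
  members <- lapply(nets, function(n) which(partition$labels == n))
  names(members) <- nets
  subs <- lapply(nets, function(n) {
    idx <- members[[n]]
    if (length(idx) < 2L) stop("network ", n, " has fewer than 2 nodes")
    tryCatch(binarize_at_density(V[idx, idx, drop = FALSE], density, scope = n),
             error = function(e) stop("network ", n, ": ", conditionMessage(e),
                                      call. = FALSE))
  })
  names(subs) <- nets
  list(partition = partition, density = density, wb = wb, subs = subs,
       members = members,
       D = graph_shortest_paths(wb),
       comm_wb = newman_modularity(wb),
       comm_subs = lapply(subs, function(s)
         tryCatch(newman_modularity(s),
                  error = function(e) stop(s$scope, " subgraph: ",
                                           conditionMessage(e), call. = FALSE))))
}

graph_family <- function(cm) paste0("graph_", conn_variant(cm))

# mean of x over scope groups defined on nodes of the whole-brain graph
scope_node_means <- function(x, st) {
  vapply(st$partition$networks, function(n) mean(x[st$members[[n]]]),
         numeric(1))
}

#' Efficiency features (36 per variant)
#'
#' From the whole-brain inverse-distance matrix: the mean over all unordered
#' node pairs (1), over within-network pairs (7) and over between-network
#' pairs (21). Plus, for each network, the global efficiency of the
#' network's own connectivity submatrix binarized at the same density
#' ("intra-efficiency", 7).
#'
#' @param cm A `connectivity_matrix` (or matrix).
#' @param partition A `network_partition`.
#' @param density Edge density for binarization (default 0.1).
#' @return A `feature_block` of 36 features.
#' @export
efficiency_features <- function(cm, partition, density = 0.1) {
  st <- graph_struct(cm, partition, density)
  feature_block(efficiency_values(st, graph_family(cm)), graph_family(cm))
}

efficiency_values <- function(st, family) {
  iD <- inverse_distance(st$D)
  ps <- pair_scope_ids(st$partition)
  vals <- iD[cbind(ps$i, ps$j)]
  scopes <- scope_labels(st$partition$networks)
  means <- as.vector(rowsum(vals, ps$scope)) / tabulate(ps$scope, nbins = 28L)
  intra <- vapply(st$partition$networks, function(n) {
    Ds <- graph_shortest_paths(st$subs[[n]])
    iDs <- inverse_distance(Ds)
    mean(iDs[upper.tri(iDs)])
  }, numeric(1))
  out <- c(mean(vals), means, intra)
  names(out) <- c(paste0(family, ":eff:", scopes),
                  paste0(family, ":eff_intra:", st$partition$networks))
  out
}

#' Clustering features (15 per variant)
#'
#' Node-level binary clustering coefficients on the whole-brain graph,
#' averaged over all nodes (1) and over each network's nodes (7); plus the
#' mean clustering of each network's own binarized subgraph
#' ("intra-clustering", 7). Nodes with degree < 2 have coefficient 0.
#'
#' @inheritParams efficiency_features
#' @return A `feature_block` of 15 features.
#' @export
clustering_features <- function(cm, partition, density = 0.1) {
  st <- graph_struct(cm, partition, density)
  feature_block(clustering_values(st, graph_family(cm)), graph_family(cm))
}

clustering_values <- function(st, family) {
  C <- local_clustering(st$wb$adjacency)
  intra <- vapply(st$partition$networks, function(n)
    mean(local_clustering(st$subs[[n]]$adjacency)), numeric(1))
  out <- c(mean(C), scope_node_means(C, st), intra)
  names(out) <- c(paste0(family, ":clust:", c("WB", st$partition$networks)),
                  paste0(family, ":clust_intra:", st$partition$networks))
  out
}

#' Modularity features (8 per variant)
#'
#' Modularity Q of the deterministic Newman partition of each of the 8
#' binary graphs: whole brain plus the 7 network subgraphs.
#'
#' @inheritParams efficiency_features
#' @return A `feature_block` of 8 features.
#' @export
modularity_features <- function(cm, partition, density = 0.1) {
  st <- graph_struct(cm, partition, density)
  feature_block(modularity_values(st, graph_family(cm)), graph_family(cm))
}

modularity_values <- function(st, family) {
  out <- c(st$comm_wb$Q, vapply(st$comm_subs, function(cm) cm$Q, numeric(1)))
  names(out) <- paste0(family, ":Q:", c("WB", st$partition$networks))
  out
}

#' Participation features (15 per variant)
#'
#' Node-level participation coefficients on the whole-brain graph (with its
#' Newman communities), averaged over all nodes (1) and per network (7);
#' plus the mean participation within each network's own subgraph using that
#' subgraph's communities ("intra-participation", 7). Isolated nodes get 0.
#'
#' @inheritParams efficiency_features
#' @return A `feature_block` of 15 features.
#' @export
participation_features <- function(cm, partition, density = 0.1) {
  st <- graph_struct(cm, partition, density)
  feature_block(participation_values(st, graph_family(cm)), graph_family(cm))
}

participation_values <- function(st, family) {
  p <- participation_coef(st$wb$adjacency, st$comm_wb$labels)
  intra <- vapply(st$partition$networks, function(n)
    mean(participation_coef(st$subs[[n]]$adjacency, st$comm_subs[[n]]$labels)),
    numeric(1))
  out <- c(mean(p), scope_node_means(p, st), intra)
  names(out) <- c(paste0(family, ":part:", c("WB", st$partition$networks)),
                  paste0(family, ":part_intra:", st$partition$networks))
  out
}

#' Graph-theoretic feature block (74 per variant)
#'
#' Concatenates, in canonical order, the 36 efficiency, 15 clustering, 8
#' modularity and 15 participation features computed on binary graphs
#' thresholded at the given edge density.
#'
#' @inheritParams efficiency_features
#' @return A `feature_block` of 74 features, family `graph_<variant>`.
#' @export
graph_features <- function(cm, partition, density = 0.1) {
  st <- graph_struct(cm, partition, density)
  family <- graph_family(cm)
  feature_block(c(efficiency_values(st, family),
                  clustering_values(st, family),
                  modularity_values(st, family),
                  participation_values(st, family)),
                family)
}
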