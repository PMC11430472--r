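test_that("binarize_at_density keeps exactly the top-k edges", {
  set.seed(1)
  P <- 400
  V <- matrix(0, P, P)
  V[upper.tri(V)] <- sample(seq_len(P * (P - 1) / 2)) / 1e6  # all distinct
  V <- V + t(V)
  g <- binarize_at_density(manual_cm(V), 0.10)
  expect_equal(sum(g$adjacency) / 2, round(0.10 * P * (P - 1) / 2))  # 7980
  expect_equal(sum(g$adjacency) / 2, 7980)
  # oracle: full sort of the off-diagonal values
  ut <- upper.tri(V)
  cutoff <- sort(V[ut], decreasing = TRUE)[7980]
  expect_true(all(V[g$adjacency == 1] >= cutoff))
  expect_equal(diag(g$adjacency), rep(0L, P), ignore_attr = TRUE)
  expect_true(isSymmetric(g$adjacency))
})

test_that("binarize_at_density handles density 1 and rejects empty graphs", {
  V <- matrix(0.5, 10, 10)
  g <- binarize_at_density(manual_cm(V), 1)
  expect_equal(sum(g$adjacency), 10 * 9)
  expect_error(binarize_at_density(manual_cm(V), 0.001), "0 edges")
})

test_that("shortest paths follow BFS geodesics with Inf for unreachable pairs", {
  D <- graph_shortest_paths(adj_path(3))
  expect_equal(D[1, 3], 2)
  D4 <- graph_shortest_paths(adj_complete(4))
  expect_equal(unname(D4[upper.tri(D4)]), rep(1, 6))
  # two disconnected edges
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1L
  D2 <- graph_shortest_paths(A)
  expect_true(is.infinite(D2[1, 3]))
  iD <- brainstates:::inverse_distance(D2)
  expect_equal(iD[1, 3], 0)
})

test_that("global efficiency of hand-checked graphs is exact", {
  expect_equal(bf_efficiency(adj_complete(4)), 1)
  # path on 3 nodes: pairs (1,2), (2,3) distance 1, (1,3) distance 2
  D <- graph_shortest_paths(adj_path(3))
  iD <- brainstates:::inverse_distance(D)
  expect_equal(mean(iD[upper.tri(iD)]), 5 / 6)
})

test_that("local clustering matches hand-counted triangles", {
  tri <- adj_complete(3)
  expect_equal(brainstates:::local_clustering(tri), rep(1, 3))
  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  expect_equal(brainstates:::local_clustering(star), rep(0, 4))
  k4m <- adj_complete(4)
  k4m[1, 2] <- k4m[2, 1] <- 0L   # K4 minus one edge
  C <- brainstates:::local_clustering(k4m)
  expect_equal(sort(C), sort(c(2 / 3, 2 / 3, 1, 1)))
  expect_equal(mean(C), 5 / 6)
})

test_that("newman_modularity is exact on canonical fixtures", {
  two_tri <- adj_two_triangles()
  cm <- newman_modularity(two_tri)
  expect_equal(max(cm$labels), 2)
  expect_equal(cm$Q, 0.5)
  expect_equal(cm$labels[1:3], rep(cm$labels[1], 3))
  expect_equal(cm$labels[4:6], rep(cm$labels[4], 3))

  full <- newman_modularity(adj_complete(5))
  expect_equal(max(full$labels), 1)
  expect_equal(full$Q, 0, tolerance = 1e-12)

  expect_error(newman_modularity(matrix(0L, 4, 4)), "edgeless")
})

test_that("newman partition attains the brute-force optimum on two cliques", {
  A <- adj_two_cliques_bridge()
  cm <- newman_modularity(A)
  bf <- bf_best_bipartition_q(A)
  expect_equal(cm$Q, bf$q, tolerance = 1e-12)
  expect_equal(max(cm$labels), 2)
  expect_equal(cm$labels[1:4], rep(cm$labels[1], 4))  # clique-aligned
  expect_equal(cm$labels[5:8], rep(cm$labels[5], 4))
})

test_that("modularity_q agrees with igraph's modularity", {
  set.seed(2)
  for (i in 1:20) {
    A <- random_connected_graph(sample(4:9, 1))
    lab <- sample(1:3, nrow(A), replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(modularity_q(A, lab), igraph::modularity(ig, lab),
                 tolerance = 1e-12)
  }
})

test_that("participation coefficient follows its formula and conventions", {
  # node 1 with 2 edges in each of 2 communities
  A <- matrix(0L, 5, 5)
  A[1, 2:5] <- A[2:5, 1] <- 1L
  labels <- c(1L, 1L, 1L, 2L, 2L)
  p <- brainstates:::participation_coef(A, labels)
  expect_equal(p[1], 0.5)
  # all edges inside own community -> 0
  B <- adj_two_triangles()
  lab2 <- c(1L, 1L, 1L, 2L, 2L, 2L)
  expect_equal(brainstates:::participation_coef(B, lab2), rep(0, 6))
  # isolated node -> 0 by convention
  C <- matrix(0L, 3, 3)
  C[1, 2] <- C[2, 1] <- 1L
  expect_equal(brainstates:::participation_coef(C, c(1L, 1L, 2L))[3], 0)
})

test_that("graph_features emits 74 deterministically ordered features", {
  p <- part28()
  sc <- simulate_scan(state_params(), p, 90, 9)
  cm <- pearson_connectivity(sc)
  fb <- graph_features(cm, p)
  expect_length(fb$values, 74)
  expect_equal(sum(startsWith(fb$names, "graph_noGSR:eff")), 36)
  expect_equal(sum(startsWith(fb$names, "graph_noGSR:clust")), 15)
  expect_equal(sum(startsWith(fb$names, "graph_noGSR:Q")), 8)
  expect_equal(sum(startsWith(fb$names, "graph_noGSR:part")), 15)
  fb2 <- graph_features(cm, p)
  expect_identical(fb$values, fb2$values)  # fully deterministic
})

test_that("graph features are invariant to consistent parcel permutation", {
  p <- part28()
  sc <- simulate_scan(state_params(), p, 90, 10)
  cm <- pearson_connectivity(sc)
  fb <- graph_features(cm, p)
  set.seed(11)
  perm <- sample(28)
  cm2 <- manual_cm(cm$values[perm, perm])
  p2 <- partition_from_labels(p$labels[perm])
  fb2 <- graph_features(cm2, p2)
  expect_equal(fb2$values, fb$values, tolerance = 1e-10)
})

test_that("whole-brain complete graph yields unit efficiency everywhere", {
  p <- part28()
  V <- matrix(0.9, 28, 28)
  fb <- efficiency_features(manual_cm(V), p, density = 1)
  eff29 <- fb$values[startsWith(fb$names, "graph_noGSR:eff:")]
  expect_equal(unname(eff29), rep(1, 29))
})
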