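# Small shared fixtures, built in code.

part28 <- function() make_partition(28)                       # 4 per network
part14 <- function() make_partition(14, stats::setNames(rep(2L, 7),
                                                        canonical_networks()))

# a partition object with an arbitrary (non-contiguous) label vector,
# used for permutation-invariance checks
partition_from_labels <- function(labels,
                                  networks = canonical_networks()) {
  structure(list(parcel_count = length(labels), labels = labels,
                 networks = networks,
                 parcel_names = sprintf("P%03d", seq_along(labels))),
            class = "network_partition")
}

# a parcel_ts built directly from a data matrix
manual_scan <- function(X, state = "baseline", subject = "S001",
                        variant = "noGSR") {
  if (is.null(colnames(X))) colnames(X) <- sprintf("P%03d", seq_len(ncol(X)))
  structure(list(data = X, subject_id = subject, state = state,
                 condition = "manual", t_points = nrow(X), variant = variant),
            class = "parcel_ts")
}

# a connectivity_matrix built directly from a symmetric matrix
manual_cm <- function(V, variant = "noGSR") {
  diag(V) <- 1
  structure(list(values = V, variant = variant), class = "connectivity_matrix")
}

# block-structured correlation matrix: `within` inside each network,
# `between` elsewhere
block_cm <- function(partition, within = 0.8, between = 0.2,
                     variant = "noGSR") {
  same <- outer(partition$labels, partition$labels, "==")
  V <- ifelse(same, within, between)
  manual_cm(V, variant)
}

adj_two_triangles <- function() {
  A <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1L
  A
}

adj_two_cliques_bridge <- function() {
  A <- matrix(0L, 8, 8)
  for (i in 1:3) for (j in (i + 1):4) A[i, j] <- A[j, i] <- 1L
  for (i in 5:7) for (j in (i + 1):8) A[i, j] <- A[j, i] <- 1L
  A[4, 5] <- A[5, 4] <- 1L
  A
}

adj_path <- function(n) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1L
  A
}

adj_complete <- function(n) {
  A <- matrix(1L, n, n)
  diag(A) <- 0L
  A
}

# tiny cohort with a strong planted VIS-SMN coupling effect, cached per
# session (used by classifier unit tests)
tiny_fixture_env <- new.env(parent = emptyenv())
tiny_planted_features <- function() {
  if (is.null(tiny_fixture_env$ft)) {
    p <- part28()
    base <- state_params()
    aty <- with_coupling_shift(base, "VIS", "SMN", 0.4)
    co <- simulate_condition(base, aty, p, 12, 120, 42)
    tiny_fixture_env$cohort <- co
    tiny_fixture_env$ft <- extract_features(co)
  }
  tiny_fixture_env$ft
}
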