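#' Row-wise sparsification of a connectivity matrix
#'
#' Fisher z-transforms the off-diagonal correlations and, per row, keeps
#' only the `round(density * (P - 1))` largest entries (signed z value),
#' zeroing the rest. Retained entries keep their z weights; the result is a
#' matrix of row connectivity profiles and need not be symmetric. Ties at
#' the row cutoff are broken by ascending column index. Correlations are
#' clipped to |r| <= 1 - 1e-7 before the z-transform so duplicated parcels
#' cannot produce infinite weights.
#'
#' @param cm A `connectivity_matrix` or square matrix of correlations.
#' @param density Fraction of entries kept per row (default 0.1).
#' @return P x P matrix of sparsified z-weighted profiles (zero diagonal).
#' @export
rowwise_sparsify <- function(cm, density = 0.1) {
  V <- as_conn_values(cm)
  P <- nrow(V)
  k <- round(density * (P - 1L))
  if (k < 1L)
    stop("density ", density, " retains 0 entries per row for P = ", P)
  Z <- atanh(pmin(pmax(V, -1 + 1e-7), 1 - 1e-7))
  diag(Z) <- -Inf
  out <- matrix(0, P, P, dimnames = dimnames(V))
  for (i in seq_len(P)) {
    ord <- order(-Z[i, ], seq_len(P))
    keep <- ord[seq_len(k)]
    out[i, keep] <- Z[i, keep]
  }
  out
}

#' Normalized-angle (cosine) affinity matrix
#'
#' Similarity of connectivity profiles between parcels:
#' `affinity(i, j) = 1 - acos(cosine(row_i, row_j)) / pi`. Lies in `[0, 1]`,
#' is symmetric, and has unit diagonal; for nonnegative profiles it is at
#' least 0.5.
#'
#' @param profiles P x P matrix of (sparsified) row profiles; every row must
#'   have at least one nonzero entry.
#' @return An object of class `affinity_matrix`: list with `values` (P x P)
#'   plus the `density`/`alpha` convention slots filled downstream.
#' @export
cosine_affinity <- function(profiles) {
  stopifnot(is.matrix(profiles))
  nrm <- sqrt(rowSums(profiles^2))
  zero <- which(nrm < 1e-300)
  if (length(zero))
    stop("zero connectivity profile for parcel(s): ",
         paste(if (is.null(rownames(profiles))) zero else rownames(profiles)[zero],
               collapse = ", "))
  cosm <- tcrossprod(profiles / nrm)
  cosm <- pmin(pmax(cosm, -1), 1)
  A <- 1 - acos(cosm) / pi
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- dimnames(profiles)
  structure(list(values = A, alpha = NA_real_, sparsity_density = NA_real_),
            class = "affinity_matrix")
}

as_affinity_values <- function(a) {
  if (inherits(a, "affinity_matrix")) a$values
  else if (is.matrix(a)) a
  else stop("expected an `affinity_matrix` or square matrix")
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Density-normalized diffusion maps: the kernel is renormalized as
#' `W' = D^-alpha W D^-alpha` (alpha = 0.5 balances the influence of
#' sampling density), the transition matrix `M = D'^-1 W'` is
#' eigendecomposed via its symmetric conjugate, and the first
#' `n_components` nontrivial eigenvectors are returned in descending
#' eigenvalue order. `diffusion_time = 0` selects multiscale weighting
#' `lambda / (1 - lambda)` (the automated diffusion-time convention);
#' positive values use `lambda^t`. Component signs are fixed so the entry
#' of largest magnitude is positive.
#'
#' @param a An `affinity_matrix` (or square nonnegative matrix); must be
#'   connected under its nonzero entries, with at least 4 parcels.
#' @param alpha Density-normalization exponent (default 0.5).
#' @param diffusion_time Diffusion time t; 0 = multiscale (default).
#' @param n_components Number of gradients retained (default 3).
#' @return An object of class `gradient_embedding`: list with `coords`
#'   (P x n_components), `eigenvalues` (nontrivial, nonincreasing),
#'   `aligned` (FALSE) and `reference_id` (NA).
#' @export
diffusion_embedding <- function(a, alpha = 0.5, diffusion_time = 0,
                                n_components = 3) {
  W <- as_affinity_values(a)
  P <- nrow(W)
  if (P < 4L) stop("need at least 4 parcels for a 3-component embedding")
  if (any(W < -1e-12)) stop("affinity matrix must be nonnegative")
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected"))
  if (comp$no > 1L)
    stop("affinity graph is disconnected (", comp$no, " components)")
  d <- rowSums(W)
  W1 <- W / (d^alpha %o% d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / sqrt(d1 %o% d1)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- e$values[seq_len(n_components + 1L)][-1L]
  psi <- e$vectors[, seq_len(n_components + 1L), drop = FALSE][, -1L, drop = FALSE] / sqrt(d1)
  wgt <- if (diffusion_time == 0) lam / (1 - pmin(lam, 1 - 1e-12))
         else lam^diffusion_time
  coords <- psi * rep(wgt, each = P)
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(W)
  colnames(coords) <- paste0("g", seq_len(n_components))
  structure(list(coords = coords, eigenvalues = lam, aligned = FALSE,
                 reference_id = NA_character_),
            class = "gradient_embedding")
}

#' @export
print.gradient_embedding <- function(x, ...) {
  cat("Gradient embedding:", nrow(x$coords), "parcels x", ncol(x$coords),
      "components; eigenvalues", paste(format(x$eigenvalues, digits = 4),
                                       collapse = ", "),
      if (isTRUE(x$aligned)) "(aligned)" else "(unaligned)", "\n")
  invisible(x)
}

embedding_coords <- function(e) {
  if (inherits(e, "gradient_embedding")) e$coords
  else if (is.matrix(e)) e
  else stop("expected a `gradient_embedding` or coordinate matrix")
}

#' Procrustes alignment of a gradient embedding to a reference
#'
#' Applies the orthogonal transform (rotation/reflection, no scaling or
#' translation) that minimizes the Frobenius distance between the embedding
#' and the reference, resolving eigenvector sign and order ambiguity.
#'
#' @param e A `gradient_embedding` (or P x k matrix).
#' @param ref Reference embedding or P x k matrix of the same shape.
#' @param reference_id Label recorded on the result.
#' @return A `gradient_embedding` with `aligned = TRUE` and attribute-free
#'   extra element `disparity` (residual sum of squares after alignment).
#' @export
procrustes_align <- function(e, ref, reference_id = "reference") {
  X <- embedding_coords(e)
  Y <- embedding_coords(ref)
  if (!all(dim(X) == dim(Y)))
    stop("embedding (", paste(dim(X), collapse = "x"),
         ") and reference (", paste(dim(Y), collapse = "x"),
         ") shapes differ")
  sv <- svd(crossprod(X, Y))
  R <- sv$u %*% t(sv$v)
  Xa <- X %*% R
  dimnames(Xa) <- dimnames(X)
  out <- if (inherits(e, "gradient_embedding")) e
         else list(coords = X, eigenvalues = rep(NA_real_, ncol(X)))
  out$coords <- Xa
  out$aligned <- TRUE
  out$reference_id <- reference_id
  out$disparity <- sum((Xa - Y)^2)
  class(out) <- "gradient_embedding"
  out
}

#' Group reference embedding from baseline scans
#'
#' Builds the alignment template the way group templates are built when no
#' external one is supplied: starting from the first embedding, all
#' embeddings are Procrustes-aligned to the current template and averaged;
#' the align-and-average step is iterated (`n_iter` = 2 by default).
#'
#' @param embeddings List of `gradient_embedding`s (same P and components).
#' @param n_iter Number of align-and-average iterations.
#' @return P x k reference coordinate matrix.
#' @export
gradient_reference <- function(embeddings, n_iter = 2) {
  stopifnot(length(embeddings) >= 1L)
  ref <- embedding_coords(embeddings[[1L]])
  for (it in seq_len(n_iter)) {
    aligned <- lapply(embeddings, function(e)
      embedding_coords(procrustes_align(e, ref)))
    ref <- Reduce(`+`, aligned) / length(aligned)
  }
  ref
}

#' Cortical gradient features (60)
#'
#' From an aligned 3-D gradient embedding: 24 range features (max minus min
#' per gradient, whole brain + 7 networks), 8 dispersion features (sum of
#' squared Euclidean distances of member parcels to their scope centroid),
#' 7 network eccentricities (squared distance from network centroid to the
#' whole-brain centroid) and 21 between-network centroid squared distances.
#'
#' @param e A `gradient_embedding` (or P x 3 matrix).
#' @param partition A `network_partition`.
#' @return A `feature_block` of 60 features, family `gradient`.
#' @export
gradient_features <- function(e, partition) {
  partition <- as_partition(partition)
  X <- embedding_coords(e)
  if (nrow(X) != partition$parcel_count)
    stop("embedding rows do not match partition")
  nets <- partition$networks
  members <- lapply(nets, function(n) which(partition$labels == n))
  names(members) <- nets
  cen_wb <- colMeans(X)
  cents <- t(vapply(nets, function(n) colMeans(X[members[[n]], , drop = FALSE]),
                    numeric(ncol(X))))
  rng <- function(M) apply(M, 2L, function(v) max(v) - min(v))
  ranges <- c(rng(X), unlist(lapply(nets, function(n)
    rng(X[members[[n]], , drop = FALSE]))))
  names(ranges) <- paste0("gradient:range:",
                          rep(c("WB", nets), each = ncol(X)),
                          ":g", rep(seq_len(ncol(X)), 8L))
  disp <- c(sum(sweep(X, 2L, cen_wb)^2),
            vapply(nets, function(n)
              sum(sweep(X[members[[n]], , drop = FALSE], 2L, cents[n, ])^2),
              numeric(1)))
  names(disp) <- paste0("gradient:disp:", c("WB", nets))
  ecc <- rowSums(sweep(cents, 2L, cen_wb)^2)
  names(ecc) <- paste0("gradient:ecc:", nets)
  pr <- network_pairs(nets)
  dist2 <- rowSums((cents[pr$a, , drop = FALSE] - cents[pr$b, , drop = FALSE])^2)
  names(dist2) <- paste0("gradient:dist:", pr$a, "-", pr$b)
  feature_block(c(ranges, disp, ecc, dist2), "gradient")
}
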