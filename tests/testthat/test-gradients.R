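test_that("rowwise_sparsify keeps the top entries per row with index tie-breaks", {
  set.seed(1)
  P <- 400
  V <- matrix(runif(P * P, -0.5, 0.9), P, P)
  V <- (V + t(V)) / 2
  diag(V) <- 1
  S <- rowwise_sparsify(manual_cm(V), 0.10)
  expect_equal(unname(rowSums(S != 0)), rep(40, P))  # round(0.1 * 399)
  # retained entries are the row-wise top-k of the z-transformed values
  z <- atanh(pmin(pmax(V, -1 + 1e-7), 1 - 1e-7))
  for (i in c(1, 57, 400)) {
    zi <- z[i, -i]
    expect_equal(sort(S[i, S[i, ] != 0]), sort(zi)[(399 - 39):399],
                 ignore_attr = TRUE)
  }
  # tie-break: equal values resolved toward smaller column index
  Vt <- matrix(0.4, 10, 10)
  St <- rowwise_sparsify(manual_cm(Vt), 0.12)   # 1 entry per row
  expect_equal(unname(apply(St != 0, 1, which)), c(2, rep(1, 9)))
})

test_that("cosine affinity matches hand-computed angles and stays in [0,1]", {
  prof <- rbind(c(1, 1, 0, 0), c(2, 2, 0, 0), c(0, 0, 3, 1))
  A <- cosine_affinity(prof)$values
  expect_equal(A[1, 2], 1)           # identical direction
  expect_equal(A[1, 3], 0.5)         # orthogonal rows
  set.seed(2)
  R <- matrix(rexp(400), 20, 20)
  AR <- cosine_affinity(R)$values
  expect_true(all(AR >= 0 & AR <= 1 + 1e-12))
  expect_true(isSymmetric(AR))
  Z <- rbind(c(1, 2), c(0, 0))
  expect_error(cosine_affinity(Z), "zero connectivity profile")
})

test_that("diffusion embedding separates a planted two-block affinity", {
  blocks <- rep(1:2, each = 10)
  W <- ifelse(outer(blocks, blocks, "=="), 0.9, 0.1)
  diag(W) <- 1
  e <- diffusion_embedding(W)
  expect_equal(ncol(e$coords), 3)
  expect_true(all(diff(e$eigenvalues) <= 1e-12))
  s <- sign(e$coords[, 1])
  expect_true(all(s[blocks == 1] == s[blocks == 1][1]))
  expect_true(all(s[blocks == 2] == s[blocks == 2][1]))
  expect_false(s[1] == s[11])
})

test_that("embedding agrees with a direct nonsymmetric eigendecomposition oracle", {
  set.seed(3)
  W <- matrix(runif(400, 0.05, 1), 20, 20)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  e <- diffusion_embedding(W, alpha = 0.5)
  # oracle: eigendecompose the row-stochastic operator M directly
  d <- rowSums(W)
  W1 <- W / outer(d^0.5, d^0.5)
  M <- W1 / rowSums(W1)
  ev <- eigen(M)
  ord <- order(-Re(ev$values))
  lam <- Re(ev$values[ord])[2:4]
  expect_equal(e$eigenvalues, lam, tolerance = 1e-8)
  for (k in 1:3) {
    v <- Re(ev$vectors[, ord[k + 1]])
    v <- v / sqrt(sum(v^2))
    u <- e$coords[, k] / sqrt(sum(e$coords[, k]^2))
    expect_equal(abs(sum(u * v)), 1, tolerance = 1e-8)
  }
  # each retained component is an eigenvector of the diffusion operator
  expect_equal(M %*% e$coords, e$coords %*% diag(lam), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(diffusion_embedding(diag(4) * 0 + diag(4)), "disconnected")
})

test_that("procrustes alignment recovers rotations and reflections exactly", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  e <- structure(list(coords = X, eigenvalues = c(3, 2, 1), aligned = FALSE,
                      reference_id = NA_character_),
                 class = "gradient_embedding")
  idd <- procrustes_align(e, X)
  expect_equal(idd$coords, X, tolerance = 1e-12)
  expect_equal(idd$disparity, 0, tolerance = 1e-12)

  flip <- X %*% diag(c(-1, 1, -1))
  ef <- e; ef$coords <- flip
  rec <- procrustes_align(ef, X)
  expect_equal(rec$coords, X, tolerance = 1e-10)

  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  er <- e; er$coords <- X %*% Q
  rec2 <- procrustes_align(er, X)
  expect_equal(rec2$coords, X, tolerance = 1e-8)
  expect_error(procrustes_align(e, X[1:10, ]), "shapes differ")
})

test_that("gradient_features emits 60 features with exact geometry", {
  p <- part28()
  X0 <- matrix(0, 28, 3)
  fb0 <- gradient_features(X0, p)
  expect_length(fb0$values, 60)
  expect_equal(unname(fb0$values), rep(0, 60))

  # place VIS at origin and SMN at distance 3 along g1
  X <- matrix(0, 28, 3)
  X[p$labels == "SMN", 1] <- 3
  fb <- gradient_features(X, p)
  expect_equal(unname(fb$values["gradient:dist:VIS-SMN"]), 9)
  expect_equal(sum(startsWith(fb$names, "gradient:range:")), 24)
  expect_equal(sum(startsWith(fb$names, "gradient:disp:")), 8)
  expect_equal(sum(startsWith(fb$names, "gradient:ecc:")), 7)
  expect_equal(sum(startsWith(fb$names, "gradient:dist:")), 21)
})

test_that("dispersion obeys the law of total variance decomposition", {
  p <- part28()
  set.seed(5)
  X <- matrix(rnorm(84), 28, 3)
  v <- gradient_features(X, p)$values
  lhs <- v["gradient:disp:WB"]
  sizes <- table(factor(p$labels, levels = p$networks))
  rhs <- sum(v[paste0("gradient:disp:", p$networks)]) +
    sum(as.numeric(sizes) * v[paste0("gradient:ecc:", p$networks)])
  expect_equal(unname(lhs), unname(rhs), tolerance = 1e-8)
})

test_that("permuted affinity gives the permuted embedding after alignment", {
  set.seed(6)
  W <- matrix(runif(625, 0.05, 1), 25, 25)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  e <- diffusion_embedding(W)
  perm <- sample(25)
  e2 <- diffusion_embedding(W[perm, perm])
  aligned <- procrustes_align(e2, e$coords[perm, ])
  expect_equal(aligned$coords, e$coords[perm, ], tolerance = 1e-6)
})

test_that("gradient reference building converges to a usable template", {
  p <- part28()
  embeds <- lapply(1:4, function(s) {
    sc <- simulate_scan(state_params(), p, 100, s)
    diffusion_embedding(cosine_affinity(rowwise_sparsify(
      pearson_connectivity(global_signal_regress(sc)))))
  })
  ref <- gradient_reference(embeds)
  expect_equal(dim(ref), c(28L, 3L))
  al <- procrustes_align(embeds[[1]], ref)
  expect_true(al$aligned)
  expect_lt(al$disparity, sum(embeds[[1]]$coords^2) * 2)
})
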