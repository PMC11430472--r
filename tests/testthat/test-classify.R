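test_that("standardization learns on training data only", {
  set.seed(1)
  X <- matrix(rnorm(200), 20, 10)
  sc <- standardize_fit(X)
  Xs <- standardize_apply(sc, X)
  expect_lt(max(abs(colMeans(Xs))), 1e-10)
  expect_lt(max(abs(apply(Xs, 2, sd) - 1)), 1e-10)
  # constant feature: clamped, maps to 0
  Xc <- cbind(X, 5)
  scc <- standardize_fit(Xc)
  expect_true(scc$clamped[11])
  expect_equal(unname(standardize_apply(scc, Xc)[, 11]), rep(0, 20))
  # altering held-out rows never changes the scaler
  expect_identical(standardize_fit(X), standardize_fit(X))
})

test_that("linear SVM separates 1-D separable data with correct orientation", {
  X <- matrix(c(-2.2, -2, -1.8, 1.8, 2, 2.2), ncol = 1)
  y <- rep(c("baseline", "atypical"), each = 3)
  m <- train_linear_svm(X, y, list(box_constraint = 100, kernel_scale = 1))
  s <- svm_score(m, X)
  expect_true(all(s[y == "atypical"] > 0))
  expect_true(all(s[y == "baseline"] < 0))
  expect_error(train_linear_svm(X, rep("baseline", 6),
                                list(box_constraint = 1, kernel_scale = 1)),
               "single class")
})

test_that("the internal trainer reproduces e1071::svm decision functions", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    p <- sample(2:12, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(c("baseline", "atypical"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    cost <- 10^runif(1, -5, 3)
    m <- train_linear_svm(X, y, list(box_constraint = cost, kernel_scale = 1))
    ref <- e1071::svm(X, factor(y, levels = c("baseline", "atypical")),
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(predict(ref, X, decision.values = TRUE), "decision.values")
    pos <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
    sref <- if (pos == "atypical") as.vector(dv) else -as.vector(dv)
    expect_equal(svm_score(m, X), sref, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("label flip negates the coefficient vector", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c("baseline", "atypical"), 10)
  h <- list(box_constraint = 1, kernel_scale = 1)
  m1 <- train_linear_svm(X, y, h)
  m2 <- train_linear_svm(X, ifelse(y == "baseline", "atypical", "baseline"), h)
  expect_equal(m1$beta, -m2$beta, tolerance = 1e-6)
  expect_equal(m1$bias, -m2$bias, tolerance = 1e-6)
})

test_that("duplicating samples at half the cost leaves the decision unchanged", {
  set.seed(3)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c("baseline", "atypical"), 10)
  m1 <- train_linear_svm(X, y, list(box_constraint = 2, kernel_scale = 1))
  m2 <- train_linear_svm(rbind(X, X), c(y, y),
                         list(box_constraint = 1, kernel_scale = 1))
  expect_equal(svm_score(m1, X), svm_score(m2, X), tolerance = 5e-3)
})

test_that("kernel scale acts as feature division before the linear kernel", {
  set.seed(4)
  X <- matrix(rnorm(80), 20, 4)
  y <- rep(c("baseline", "atypical"), 10)
  m1 <- train_linear_svm(X, y, list(box_constraint = 4, kernel_scale = 2))
  m2 <- train_linear_svm(X / 2, y, list(box_constraint = 4, kernel_scale = 1))
  expect_equal(svm_score(m1, X), svm_score(m2, X / 2), tolerance = 1e-8)
})

test_that("inner grid search selects from the grid with deterministic tie-breaks", {
  set.seed(5)
  X <- matrix(rnorm(72), 24, 3)
  X[13:24, ] <- X[13:24, ] + 4           # strongly separable
  y <- rep(c("baseline", "atypical"), each = 12)
  subj <- rep(sprintf("S%02d", 1:12), 2)
  one <- data.frame(box_constraint = 0.5, kernel_scale = 2)
  got <- inner_grid_search(X, y, subj, grid = one)
  expect_equal(got$box_constraint, 0.5)
  expect_equal(got$kernel_scale, 2)

  set.seed(6)
  sel <- inner_grid_search(X, y, subj)
  g <- hyper_grid()
  expect_true(any(g$box_constraint == sel$box_constraint &
                    g$kernel_scale == sel$kernel_scale))
  set.seed(6)
  sel2 <- inner_grid_search(X, y, subj)
  expect_identical(sel, sel2)
})

test_that("nested_cv partitions subjects and keeps pairs together", {
  ft <- tiny_planted_features()
  plan <- cv_plan(outer_k = 10, inner_k = 3, n_repeats = 2, seed = 9)
  folds <- brainstates:::build_cv_folds(ft$subject_id, plan)
  for (r in seq_along(folds)) {
    of <- folds[[r]]$outer
    expect_equal(sort(unique(of)), 1:10)
    # every scan in exactly one fold; pairs share a fold
    expect_length(of, length(ft$subject_id))
    expect_true(all(tapply(of, ft$subject_id, function(v)
      length(unique(v))) == 1))
  }
})

test_that("nested_cv is deterministic and leakage-free", {
  ft <- tiny_planted_features()
  X <- ft$x[, ft$families == "conn_GSR"]
  plan <- cv_plan(outer_k = 5, inner_k = 3, n_repeats = 1, seed = 13)
  r1 <- nested_cv(X, ft$state, ft$subject_id, plan, family = "conn_GSR")
  r2 <- nested_cv(X, ft$state, ft$subject_id, plan, family = "conn_GSR")
  expect_identical(lapply(r1[[1]], `[[`, "scores"),
                   lapply(r2[[1]], `[[`, "scores"))
  expect_identical(lapply(r1[[1]], function(f) f$model$beta),
                   lapply(r2[[1]], function(f) f$model$beta))
  # corrupt the test rows of fold 1: fold-1 model must not change
  folds <- brainstates:::build_cv_folds(ft$subject_id, plan)
  te1 <- which(folds[[1]]$outer == 1)
  Xc <- X
  Xc[te1, ] <- matrix(rnorm(length(te1) * ncol(X)) * 100,
                      nrow = length(te1))
  r3 <- brainstates:::run_family_cv(Xc, ft$state, folds, "conn_GSR")
  expect_identical(r3[[1]][[1]]$model$beta, r1[[1]][[1]]$model$beta)
  expect_identical(r3[[1]][[1]]$model$scaler, r1[[1]][[1]]$model$scaler)
  expect_identical(r3[[1]][[1]]$hyper, r1[[1]][[1]]$hyper)
})

test_that("nested_cv refuses too few subjects", {
  set.seed(7)
  X <- matrix(rnorm(8 * 3), 8, 3)
  y <- rep(c("baseline", "atypical"), 4)
  subj <- rep(sprintf("S%d", 1:4), each = 2)
  expect_error(nested_cv(X, y, subj, cv_plan(outer_k = 10, n_repeats = 1)),
               "at least 10 subjects")
})

test_that("ensemble_predict implements majority vote and score summation", {
  mk <- function(score) {
    structure(list(beta = stats::setNames(score, "f"), bias = 0,
                   hyper = list(box_constraint = 1, kernel_scale = 1),
                   scaler = list(mean = 0, sd = 1,
                                 clamped = FALSE),
                   feature_names = "f", family = "x"),
              class = "trained_model")
  }
  X1 <- matrix(1, 1, 1, dimnames = list(NULL, "f"))
  base <- lapply(c(0.2, 0.2, 0.2, -0.1, -0.1), mk)
  Xl <- rep(list(X1), 5)
  expect_equal(ensemble_predict(base, Xl, "soft"), 0.4, tolerance = 1e-12)
  # hard voting: scores (+,+,+,-,-) -> majority atypical
  expect_equal(ensemble_predict(base, Xl, "hard"), "atypical")
  base2 <- lapply(c(-0.2, 0.3, -0.2, -0.1, 0.1), mk)
  expect_equal(ensemble_predict(base2, Xl, "hard"), "baseline")
})
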