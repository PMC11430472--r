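#' Hyperparameter grid for the linear SVM
#'
#' Powers of 10: box constraint C in 10^-6..10^3 (10 values) crossed with
#' kernel scale in 10^-4..10^2 (7 values), 70 combinations.
#'
#' @return Data frame with columns `box_constraint`, `kernel_scale`.
#' @export
hyper_grid <- function() {
  g <- expand.grid(box_constraint = 10^(-6:3), kernel_scale = 10^(-4:2))
  g[order(g$box_constraint, g$kernel_scale), , drop = FALSE]
}

#' Fit / apply per-feature standardization
#'
#' `standardize_fit` learns per-feature mean and standard deviation on a
#' training matrix; `standardize_apply` transforms any matrix with those
#' training parameters (never refitting, so held-out data cannot leak).
#' Features with (near-)zero training variance get their SD clamped to 1 and
#' are flagged, so they map to constant 0.
#'
#' @param X Samples x features numeric matrix.
#' @return `standardize_fit`: list with `mean`, `sd`, `clamped` (logical).
#' @export
standardize_fit <- function(X) {
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  clamped <- !is.finite(s) | s < 1e-12
  s[clamped] <- 1
  list(mean = m, sd = s, clamped = clamped)
}

#' @rdname standardize_fit
#' @param scaler A scaler from `standardize_fit`.
#' @export
standardize_apply <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mean), 2L, scaler$sd, "/")
}

as_pm1 <- function(y, positive = "atypical") {
  ifelse(y == positive, 1, -1)
}

# Direct call into libsvm's C-classification trainer (the routine behind
# e1071::svm) with linear kernel and default solver settings
# (tolerance 1e-3, cache 40 MB, shrinking). The nested CV performs tens of
# thousands of small fits; bypassing the wrapper's data-frame handling
# makes them cheap. Equivalence with e1071::svm is asserted in the tests.
# yint: integer class codes (order of first appearance decides libsvm's
# positive class, exactly as in the wrapper).
libsvm_linear_c <- function(X, yint, cost) {
  nr <- nrow(X)
  nc <- ncol(X)
  err <- paste(rep(" ", 255), collapse = "")
  cret <- .C(get("R_svmtrain", envir = asNamespace("e1071")),
             as.double(t(X)), as.integer(nr), as.integer(nc),
             as.double(yint), as.integer(0), as.integer(0),
             as.integer(0),            # type: C-classification
             as.integer(0),            # kernel: linear
             as.integer(3), as.double(1 / nc), as.double(0),
             as.double(cost), as.double(0.5),
             integer(0), double(0), as.integer(0),
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1), as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = err)
  if (!identical(cret$error, err))
    stop("libsvm: ", trimws(cret$error))
  nsv <- cret$nr
  idx <- cret$index[seq_len(nsv)]
  alpha <- cret$coefs[seq_len(nsv)]
  list(beta = as.vector(crossprod(X[idx, , drop = FALSE], alpha)),
       bias = -cret$rho[1L],
       positive_code = cret$labels[1L])
}

#' Train a linear soft-margin SVM
#'
#' Fits the standard soft-margin linear classifier (0.5 ||beta||^2 +
#' C * sum of hinge losses) on features divided by the kernel scale, via
#' libsvm. The decision score of the returned model is
#' `score(x) = <beta, ((x - mean)/sd) / kernel_scale> + bias`, oriented so
#' positive scores mean the atypical state. Deterministic for fixed input.
#'
#' @param X Standardized samples x features matrix.
#' @param y Labels ("baseline"/"atypical"); both classes must be present.
#' @param hyper List with `box_constraint` and `kernel_scale`.
#' @param family Feature-family tag stored on the model.
#' @param scaler Optional standardization parameters stored on the model.
#' @return An object of class `trained_model` with elements `beta`, `bias`,
#'   `hyper`, `scaler`, `feature_names`, `family`.
#' @export
train_linear_svm <- function(X, y, hyper, family = "features", scaler = NULL) {
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  Xs <- X / hyper$kernel_scale
  yint <- ifelse(y == "atypical", 2L, 1L)
  fit <- libsvm_linear_c(Xs, yint, hyper$box_constraint)
  beta <- fit$beta
  bias <- fit$bias
  # libsvm orients the decision value toward the class of the first
  # training row; normalise so positive score = atypical.
  if (fit$positive_code != 2L) {
    beta <- -beta
    bias <- -bias
  }
  names(beta) <- colnames(X)
  structure(
    list(beta = beta, bias = bias, hyper = hyper, scaler = scaler,
         feature_names = colnames(X), family = family),
    class = "trained_model")
}

#' Decision scores of a trained model
#'
#' @param model A `trained_model`.
#' @param X Feature matrix on the same scale the model was trained on
#'   (already standardized), or raw if the model carries a scaler and
#'   `raw = TRUE`.
#' @param raw If TRUE, apply the model's stored scaler first.
#' @return Numeric vector of decision scores (positive = atypical).
#' @export
svm_score <- function(model, X, raw = FALSE) {
  if (raw) {
    if (is.null(model$scaler)) stop("model carries no scaler")
    if (!is.null(model$feature_names) && !is.null(colnames(X)))
      X <- X[, model$feature_names, drop = FALSE]
    X <- standardize_apply(model$scaler, X)
  }
  if (!is.null(names(model$beta)) && !is.null(colnames(X)))
    X <- X[, names(model$beta), drop = FALSE]
  drop(X %*% model$beta / model$hyper$kernel_scale) + model$bias
}

# Deal shuffled subjects into k folds (round-robin). rng state is the
# caller's responsibility.
subject_folds <- function(subjects, k) {
  u <- unique(subjects)
  if (length(u) < k) stop("need at least ", k, " subjects for ", k, " folds")
  shuffled <- sample(u)
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(u)), shuffled)
  unname(fold_of[subjects])
}

#' Inner grid search for SVM hyperparameters
#'
#' Exhaustive search over the hyperparameter grid by subject-grouped
#' `inner_k`-fold cross-validation, selecting the combination with minimal
#' mean hinge loss on the validation folds. Ties break toward smaller box
#' constraint, then smaller kernel scale. For a linear kernel, grid points
#' with equal effective cost C / scale^2 yield identical decision
#' functions; the search exploits this to fit each distinct effective cost
#' once per fold.
#'
#' @param X Standardized training matrix.
#' @param y Labels.
#' @param subjects Subject id per row (folds never split a subject).
#' @param grid Hyperparameter grid (default [hyper_grid()]).
#' @param inner_k Number of inner folds (default 3).
#' @param folds Optional precomputed fold id per row; if NULL, drawn from
#'   the current RNG state.
#' @return Single-row list with `box_constraint`, `kernel_scale`.
#' @export
inner_grid_search <- function(X, y, subjects, grid = hyper_grid(),
                              inner_k = 3, folds = NULL) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (is.null(folds)) folds <- subject_folds(subjects, inner_k)
  eff <- grid$box_constraint / grid$kernel_scale^2
  ueff <- sort(unique(eff))
  ypm <- as_pm1(y)
  losses <- matrix(NA_real_, inner_k, nrow(grid))
  used <- logical(inner_k)
  for (f in seq_len(inner_k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) {
      warning("inner fold ", f, " skipped (single-class training split)")
      next
    }
    used[f] <- TRUE
    hl <- numeric(length(ueff))
    for (ei in seq_along(ueff)) {
      m <- train_linear_svm(X[tr, , drop = FALSE], y[tr],
                            list(box_constraint = ueff[ei], kernel_scale = 1))
      sc <- svm_score(m, X[!tr, , drop = FALSE])
      hl[ei] <- mean(pmax(0, 1 - ypm[!tr] * sc))
    }
    losses[f, ] <- hl[match(eff, ueff)]
  }
  if (!any(used)) stop("all inner folds skipped; cannot select hyperparameters")
  mean_loss <- colMeans(losses[used, , drop = FALSE])
  best <- min(mean_loss)
  cand <- which(mean_loss <= best + 1e-12)
  cand <- cand[order(grid$box_constraint[cand], grid$kernel_scale[cand])]
  list(box_constraint = grid$box_constraint[cand[1L]],
       kernel_scale = grid$kernel_scale[cand[1L]])
}
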