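#' Repeated nested cross-validation plan
#'
#' Subject-grouped outer/inner fold design: outer folds partition subjects
#' (a subject's paired scans never straddle train and test), each outer
#' training set is standardized and searched over the hyperparameter grid
#' by inner cross-validation, and the whole procedure is repeated with
#' re-randomized partitions.
#'
#' @param outer_k Outer folds (default 10).
#' @param inner_k Inner folds (default 3).
#' @param n_repeats Repetitions of the full nested procedure (default 50).
#' @param seed Integer seed governing all fold randomness.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(outer_k = 10, inner_k = 3, n_repeats = 50, seed = 1) {
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

# Precompute every fold assignment for all repetitions from one seeded
# stream, so that all feature families see identical partitions.
build_cv_folds <- function(subjects, plan) {
  u <- unique(subjects)
  if (length(u) < plan$outer_k)
    stop("need at least ", plan$outer_k, " subjects for ", plan$outer_k,
         "-fold outer cross-validation (got ", length(u), ")")
  set.seed(plan$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  lapply(seq_len(plan$n_repeats), function(r) {
    outer <- subject_folds(subjects, plan$outer_k)
    inner <- lapply(seq_len(plan$outer_k), function(f) {
      tr <- which(outer != f)
      stats::setNames(subject_folds(subjects[tr], plan$inner_k), NULL)
    })
    list(outer = outer, inner = inner)
  })
}

# Nested CV for one feature matrix given precomputed folds.
run_family_cv <- function(X, y, folds_all, family, grid = hyper_grid()) {
  lapply(seq_along(folds_all), function(r) {
    fr <- folds_all[[r]]
    lapply(seq_len(max(fr$outer)), function(f) {
      tr <- which(fr$outer != f)
      te <- which(fr$outer == f)
      scaler <- standardize_fit(X[tr, , drop = FALSE])
      Xtr <- standardize_apply(scaler, X[tr, , drop = FALSE])
      hyper <- inner_grid_search(Xtr, y[tr], subjects = NULL, grid = grid,
                                 inner_k = max(fr$inner[[f]]),
                                 folds = fr$inner[[f]])
      model <- train_linear_svm(Xtr, y[tr], hyper, family = family,
                                scaler = scaler)
      Xte <- standardize_apply(scaler, X[te, , drop = FALSE])
      list(model = model, repetition = r, fold = f, test_idx = te,
           scores = svm_score(model, Xte), hyper = hyper)
    })
  })
}

#' Nested cross-validation for one feature family
#'
#' Runs the full repeated nested CV (outer performance folds, inner
#' hyperparameter search by minimal mean hinge loss, refit on the complete
#' outer training set) for a single feature matrix. Fold randomness comes
#' entirely from `plan$seed`.
#'
#' @param X Samples x features matrix.
#' @param y Labels ("baseline"/"atypical").
#' @param subjects Subject id per row.
#' @param plan A [cv_plan()].
#' @param family Family tag stored on the models.
#' @param grid Hyperparameter grid.
#' @return List over repetitions of lists over outer folds; each element
#'   carries `model`, `test_idx`, `scores` and the selected `hyper`.
#' @export
nested_cv <- function(X, y, subjects, plan, family = "features",
                      grid = hyper_grid()) {
  stopifnot(nrow(X) == length(y), length(subjects) == length(y))
  folds_all <- build_cv_folds(subjects, plan)
  run_family_cv(X, y, folds_all, family, grid)
}

#' Ensemble prediction from fold-matched base models
#'
#' Combines the five family base models of one outer fold. `"soft"` sums
#' their decision scores; `"hard"` takes the majority class over their
#' sign predictions (five voters, no ties); `"integration"` scores with a
#' single model trained on the concatenated 324-feature block (pass that
#' model as `integration_model`).
#'
#' @param base_models List of `trained_model`s (one per family).
#' @param X_list List of raw feature matrices matched to `base_models`
#'   (each model applies its own stored scaler).
#' @param mode One of "integration", "hard", "soft".
#' @param integration_model The concatenated-feature model (integration
#'   mode only).
#' @param X_integration Raw concatenated feature matrix (integration mode).
#' @return Soft mode: summed scores. Hard mode: character labels.
#'   Integration mode: scores of the integration model.
#' @export
ensemble_predict <- function(base_models, X_list, mode = c("soft", "hard", "integration"),
                             integration_model = NULL, X_integration = NULL) {
  mode <- match.arg(mode)
  if (mode == "integration") {
    if (is.null(integration_model) || is.null(X_integration))
      stop("integration mode needs `integration_model` and `X_integration`")
    return(svm_score(integration_model, X_integration, raw = TRUE))
  }
  folds <- vapply(base_models, function(m) {
    f <- attr(m, "fold_id")
    if (is.null(f)) NA_character_ else f
  }, character(1))
  if (length(unique(stats::na.omit(folds))) > 1L)
    stop("base models come from different folds: ",
         paste(unique(stats::na.omit(folds)), collapse = ", "))
  S <- vapply(seq_along(base_models), function(i)
    svm_score(base_models[[i]], X_list[[i]], raw = TRUE),
    numeric(nrow(X_list[[1L]])))
  S <- matrix(S, ncol = length(base_models))
  if (mode == "soft") return(rowSums(S))
  if (length(base_models) %% 2L == 0L)
    warning("hard voting with an even number of voters can tie; ties go to baseline")
  votes <- rowSums(S > 0)
  ifelse(votes > length(base_models) / 2, "atypical", "baseline")
}
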