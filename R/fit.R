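#' Fit the brain-state classification pipeline
#'
#' Trains linear SVM base models on each of the five feature families under
#' repeated subject-grouped nested cross-validation (outer folds for
#' performance, inner folds for grid hyperparameter search by minimal mean
#' hinge loss), plus the three ensemble strategies: feature integration
#' (one model on all 324 features), hard voting and soft voting over the
#' five fold-matched base models. All families and ensembles share the same
#' fold partitions within a repetition.
#'
#' Balanced accuracy is computed with a threshold search over \[-1, 1\]
#' (see [optimize_threshold()]); summed soft-voting scores are divided by
#' the number of base models before the search. The headline estimate pools
#' outer-test scores within each repetition and averages over repetitions;
#' per-fold metrics are stored as well. `threshold = "fixed"` instead
#' scores at a fixed threshold of 0 (no search), which removes the
#' optimistic bias of optimizing on the evaluation scores.
#'
#' @param features A `brainstate_features` object (see [extract_features()]),
#'   or any list with elements `x`, `state`, `subject_id`, `families`.
#' @param plan A [cv_plan()].
#' @param grid Hyperparameter grid (default [hyper_grid()]).
#' @param threshold "optimized" (default) or "fixed".
#' @return An object of class `brainstate_cv` with elements:
#'   \describe{
#'     \item{results}{data frame of per-repetition pooled metrics per
#'       family/ensemble (balanced accuracy, AUC, threshold, confusion).}
#'     \item{fold_results}{the same metrics per outer fold.}
#'     \item{summary}{mean balanced accuracy / AUC per family.}
#'     \item{importance}{[feature_importance()] of the integration models.}
#'     \item{models}{all trained fold models by family.}
#'   }
#' @seealso [predict.brainstate_cv()], [transfer_matrix()]
#' @export
brainstate_cv <- function(features, plan = cv_plan(), grid = hyper_grid(),
                          threshold = c("optimized", "fixed")) {
  threshold <- match.arg(threshold)
  X <- features$x
  y <- features$state
  subjects <- features$subject_id
  fams <- features$families
  base_families <- unique(fams)
  folds_all <- build_cv_folds(subjects, plan)
  runs <- lapply(base_families, function(fam)
    run_family_cv(X[, fams == fam, drop = FALSE], y, folds_all, fam, grid))
  names(runs) <- base_families
  runs$integration <- run_family_cv(X, y, folds_all, "integration", grid)
  n_base <- length(base_families)

  # per rep/fold score table for every family and the voting ensembles
  fold_rows <- list()
  rep_rows <- list()
  eval_scores <- function(scores, labels, nb) {
    if (threshold == "optimized") {
      ot <- optimize_threshold(scores, labels, n_base = nb)
    } else {
      p <- scores / nb > 0
      cc <- confusion_counts(ifelse(p, "atypical", "baseline"), labels)
      ot <- list(threshold = 0, balanced_accuracy = balanced_accuracy(cc),
                 confusion = cc)
    }
    c(list(auc = auc_score(scores, labels)), ot)
  }
  for (r in seq_len(plan$n_repeats)) {
    base_sc <- lapply(base_families, function(fam)
      lapply(runs[[fam]][[r]], `[[`, "scores"))
    names(base_sc) <- base_families
    int_sc <- lapply(runs$integration[[r]], `[[`, "scores")
    test_idx <- lapply(runs$integration[[r]], `[[`, "test_idx")
    soft_sc <- lapply(seq_along(int_sc), function(f)
      Reduce(`+`, lapply(base_sc, `[[`, f)))
    vote_sc <- lapply(seq_along(int_sc), function(f)
      Reduce(`+`, lapply(base_sc, function(s) as.numeric(s[[f]] > 0))))
    all_fams <- c(base_families, "integration", "soft_voting", "hard_voting")
    for (fam in all_fams) {
      nb <- if (fam == "soft_voting") n_base else 1
      sc_list <- switch(fam, integration = int_sc, soft_voting = soft_sc,
                        hard_voting = vote_sc, base_sc[[fam]])
      for (f in seq_along(sc_list)) {
        labs <- y[test_idx[[f]]]
        row <- if (fam == "hard_voting") {
          cc <- confusion_counts(
            ifelse(sc_list[[f]] > n_base / 2, "atypical", "baseline"), labs)
          list(auc = auc_score(sc_list[[f]], labs), threshold = NA_real_,
               balanced_accuracy = balanced_accuracy(cc), confusion = cc)
        } else eval_scores(sc_list[[f]], labs, nb)
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          family = fam, repetition = r, fold = f,
          balanced_accuracy = row$balanced_accuracy, auc = row$auc,
          threshold = row$threshold,
          tp = row$confusion[["tp"]], fn = row$confusion[["fn"]],
          tn = row$confusion[["tn"]], fp = row$confusion[["fp"]],
          stringsAsFactors = FALSE)
      }
      pooled <- unlist(sc_list)
      plabs <- y[unlist(test_idx)]
      prow <- if (fam == "hard_voting") {
        cc <- confusion_counts(
          ifelse(pooled > n_base / 2, "atypical", "baseline"), plabs)
        list(auc = auc_score(pooled, plabs), threshold = NA_real_,
             balanced_accuracy = balanced_accuracy(cc), confusion = cc)
      } else eval_scores(pooled, plabs, nb)
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        family = fam, repetition = r,
        balanced_accuracy = prow$balanced_accuracy, auc = prow$auc,
        threshold = prow$threshold,
        tp = prow$confusion[["tp"]], fn = prow$confusion[["fn"]],
        tn = prow$confusion[["tn"]], fp = prow$confusion[["fp"]],
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rep_rows)
  fold_results <- do.call(rbind, fold_rows)
  summ <- stats::aggregate(cbind(balanced_accuracy, auc) ~ family, results, mean)
  summ <- summ[match(c(base_families, "integration", "soft_voting",
                       "hard_voting"), summ$family), ]
  rownames(summ) <- NULL
  int_models <- unlist(lapply(runs$integration, function(rep_)
    lapply(rep_, `[[`, "model")), recursive = FALSE)
  structure(
    list(results = results, fold_results = fold_results, summary = summ,
         importance = feature_importance(int_models),
         models = runs, plan = plan, threshold_mode = threshold,
         condition = features$condition, families = fams,
         feature_names = colnames(X), n_base = n_base,
         labels = y, subjects = subjects, call = match.call()),
    class = "brainstate_cv")
}

#' @export
print.brainstate_cv <- function(x, ...) {
  cat("Brain-state nested-CV classifier  (condition: ", x$condition, ")\n",
      sep = "")
  cat(sprintf("  %d scans, %d subjects; outer %d-fold x inner %d-fold, %d repetition(s)\n",
              length(x$labels), length(unique(x$subjects)),
              x$plan$outer_k, x$plan$inner_k, x$plan$n_repeats))
  cat("  threshold mode:", x$threshold_mode, "\n\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
summary.brainstate_cv <- function(object, ...) {
  s <- object$summary
  sds <- stats::aggregate(cbind(balanced_accuracy, auc) ~ family,
                          object$results, stats::sd)
  s$ba_sd <- sds$balanced_accuracy[match(s$family, sds$family)]
  s$auc_sd <- sds$auc[match(s$family, sds$family)]
  structure(list(summary = s, importance = utils::head(object$importance, 10L),
                 plan = object$plan, condition = object$condition),
            class = "summary.brainstate_cv")
}

#' @export
print.summary.brainstate_cv <- function(x, ...) {
  cat("Per-family performance (mean over repetitions, pooled outer-test scores):\n")
  print(x$summary, digits = 3)
  cat("\nTop features by importance:\n")
  print(x$importance)
  invisible(x)
}

#' Extract feature importance from a fitted pipeline
#'
#' `coef()` on a `brainstate_cv` returns the [feature_importance()] table
#' of the integration-mode models (mean normalized absolute SVM
#' coefficients).
#'
#' @param object A `brainstate_cv`.
#' @param ... Unused.
#' @return An `importance_table`.
#' @export
coef.brainstate_cv <- function(object, ...) {
  object$importance
}

#' Predict brain state for new scans
#'
#' Scores new data with every stored fold-model set, soft-voting the five
#' base families, and averages across fold-model sets.
#'
#' @param object A `brainstate_cv`.
#' @param newdata A `brainstate_features` object with the same feature
#'   names.
#' @param type "score" (mean soft-voting score on the base-model scale) or
#'   "label" (sign at threshold 0).
#' @param ... Unused.
#' @return Numeric scores or character labels, one per scan.
#' @export
predict.brainstate_cv <- function(object, newdata,
                                  type = c("score", "label"), ...) {
  type <- match.arg(type)
  S <- transfer_scores(object, newdata)
  sc <- rowMeans(S) / object$n_base
  if (type == "score") return(sc)
  ifelse(sc > 0, "atypical", "baseline")
}

# soft-voting scores of every fold-model set on a new feature table:
# scans x (repetitions * folds) matrix of summed base scores.
transfer_scores <- function(object, newdata) {
  if (!identical(colnames(newdata$x), object$feature_names))
    stop("feature names of `newdata` do not match the fitted model; missing: ",
         paste(utils::head(setdiff(object$feature_names, colnames(newdata$x))),
               collapse = ", "))
  base_families <- setdiff(names(object$models), "integration")
  X <- newdata$x
  nsets <- object$plan$n_repeats * object$plan$outer_k
  S <- matrix(0, nrow(X), nsets)
  for (fam in base_families) {
    Xf <- X[, object$families == fam, drop = FALSE]
    k <- 0L
    for (r in seq_len(object$plan$n_repeats)) {
      for (f in seq_along(object$models[[fam]][[r]])) {
        k <- k + 1L
        S[, k] <- S[, k] +
          svm_score(object$models[[fam]][[r]][[f]]$model, Xf, raw = TRUE)
      }
    }
  }
  S
}

#' Cross-condition transfer matrix
#'
#' Every trained fold-model set from condition A (soft voting over its five
#' base models, using A's scalers) scores all scans of condition B; the
#' cell metric is the mean balanced accuracy / AUC over fold-model sets.
#' Diagonal cells reuse the within-condition nested-CV pooled results.
#'
#' @param fits Named list of `brainstate_cv` objects (train conditions).
#' @param features_list Named list of `brainstate_features` (test
#'   conditions); names must match `fits`.
#' @return Data frame with columns `train`, `test`, `balanced_accuracy`,
#'   `auc`.
#' @export
transfer_matrix <- function(fits, features_list) {
  stopifnot(length(names(fits)) == length(fits),
            all(names(fits) %in% names(features_list)))
  rows <- list()
  for (a in names(fits)) {
    for (b in names(features_list)) {
      if (a == b) {
        s <- fits[[a]]$summary
        i <- match("soft_voting", s$family)
        rows[[paste(a, b)]] <- data.frame(
          train = a, test = b,
          balanced_accuracy = s$balanced_accuracy[i], auc = s$auc[i],
          stringsAsFactors = FALSE)
        next
      }
      S <- transfer_scores(fits[[a]], features_list[[b]])
      labs <- features_list[[b]]$state
      nb <- fits[[a]]$n_base
      ba <- numeric(ncol(S))
      au <- numeric(ncol(S))
      for (k in seq_len(ncol(S))) {
        if (fits[[a]]$threshold_mode == "optimized") {
          ba[k] <- optimize_threshold(S[, k], labs, n_base = nb)$balanced_accuracy
        } else {
          cc <- confusion_counts(ifelse(S[, k] / nb > 0, "atypical", "baseline"),
                                 labs)
          ba[k] <- balanced_accuracy(cc)
        }
        au[k] <- auc_score(S[, k], labs)
      }
      rows[[paste(a, b)]] <- data.frame(
        train = a, test = b, balanced_accuracy = mean(ba), auc = mean(au),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Boxplot of per-repetition balanced accuracy by model
#'
#' @param x A `brainstate_cv`.
#' @param metric "balanced_accuracy" or "auc".
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.brainstate_cv <- function(x, metric = "balanced_accuracy", ...) {
  r <- x$results
  fams <- unique(r$family)
  graphics::boxplot(r[[metric]] ~ factor(r$family, levels = fams),
                    xlab = "model", ylab = gsub("_", " ", metric),
                    las = 2, ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
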