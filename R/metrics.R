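#' Balanced accuracy from confusion counts
#'
#' The average of sensitivity and specificity,
#' `0.5 * (TP/(TP+FN) + TN/(TN+FP))`, robust to class imbalance. Positive
#' class is the atypical state.
#'
#' @param tp,fn,tn,fp Confusion counts, or pass a single named vector/list
#'   as `tp` with elements tp, fn, tn, fp.
#' @return Scalar in \[0, 1\].
#' @examples
#' balanced_accuracy(3, 1, 2, 2) # 0.625
#' @export
balanced_accuracy <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.null(fn)) {
    cc <- tp
    tp <- cc[["tp"]]; fn <- cc[["fn"]]; tn <- cc[["tn"]]; fp <- cc[["fp"]]
  }
  if (tp + fn == 0) stop("no positive samples: sensitivity undefined")
  if (tn + fp == 0) stop("no negative samples: specificity undefined")
  0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

#' Confusion counts for predicted labels
#' @param pred,labels Character vectors of predicted and true labels.
#' @param positive Positive class (default "atypical").
#' @return Named vector (tp, fn, tn, fp).
#' @export
confusion_counts <- function(pred, labels, positive = "atypical") {
  p <- pred == positive
  y <- labels == positive
  c(tp = sum(p & y), fn = sum(!p & y), tn = sum(!p & !y), fp = sum(p & !y))
}

#' Threshold search maximizing balanced accuracy
#'
#' Evaluates balanced accuracy at 201 evenly spaced thresholds in
#' \[-1, +1\] plus all midpoints of adjacent sorted scores (clipped to the
#' range), predicting atypical when score > threshold. Returns the
#' maximizing threshold (smallest on ties). Summed soft-voting scores
#' should be divided by the number of base models first (`n_base`), so
#' they live on the base-score scale.
#'
#' @param scores Finite decision scores.
#' @param labels True labels; both classes must be present.
#' @param n_base Number of base models whose scores were summed (default 1).
#' @return List with `threshold`, `balanced_accuracy` and `confusion`.
#' @export
optimize_threshold <- function(scores, labels, n_base = 1) {
  stopifnot(all(is.finite(scores)))
  y <- labels == "atypical"
  if (!any(y) || all(y)) stop("both classes must be present")
  s <- scores / n_base
  ss <- sort(s)
  mids <- (ss[-1L] + ss[-length(ss)]) / 2
  cand <- sort(unique(c(seq(-1, 1, length.out = 201L),
                        pmin(pmax(mids, -1), 1))))
  npos <- sum(y)
  nneg <- sum(!y)
  ba <- vapply(cand, function(t) {
    p <- s > t
    0.5 * (sum(p & y) / npos + sum(!p & !y) / nneg)
  }, numeric(1))
  i <- which.max(ba)  # which.max returns the first (smallest) maximizer
  p <- s > cand[i]
  list(threshold = cand[i], balanced_accuracy = ba[i],
       confusion = confusion_counts(ifelse(p, "atypical", "baseline"), labels))
}

#' Rank-based AUC (Mann-Whitney)
#'
#' Area under the ROC curve computed from rank statistics; tied scores
#' count one half.
#'
#' @param scores Decision scores (higher = more atypical).
#' @param labels True labels; both classes must be present.
#' @return Scalar in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- labels == "atypical"
  if (!any(y) || all(y)) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - sum(y) * (sum(y) + 1) / 2) / (sum(y) * sum(!y))
}

#' Feature importance from absolute SVM coefficients
#'
#' Per model, the absolute beta coefficients are normalized to sum to one
#' (making models with different margins commensurable); the table is the
#' entrywise mean over models, sorted descending.
#'
#' @param models List of `trained_model`s sharing the same feature names
#'   (typically all integration-mode fold models of a meta-condition).
#' @return An object of class `importance_table`: data frame with columns
#'   `feature` and `importance` (nonnegative, summing to 1), attribute
#'   `n_models_averaged`.
#' @export
feature_importance <- function(models) {
  if (!length(models)) stop("empty model list")
  nm <- models[[1L]]$feature_names
  ok <- vapply(models, function(m) identical(m$feature_names, nm), logical(1))
  if (!all(ok)) stop("models do not share feature names")
  W <- vapply(models, function(m) {
    a <- abs(m$beta)
    s <- sum(a)
    if (s < 1e-300) rep(NA_real_, length(a)) else a / s
  }, numeric(length(nm)))
  W <- matrix(W, nrow = length(nm))
  keep <- colSums(is.na(W)) == 0L
  if (!any(keep)) stop("all models have zero coefficient vectors")
  if (!all(keep)) warning(sum(!keep), " model(s) with all-zero coefficients excluded")
  imp <- rowMeans(W[, keep, drop = FALSE])
  out <- data.frame(feature = nm, importance = imp, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  structure(out, n_models_averaged = sum(keep),
            class = c("importance_table", "data.frame"))
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat("Feature importance (mean normalized |beta| over",
      attr(x, "n_models_averaged"), "models)\n")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more features\n")
  invisible(x)
}
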