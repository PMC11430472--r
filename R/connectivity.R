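#' Global signal regression at the parcel level
#'
#' Regresses the cross-parcel mean time course (the "global signal") out of
#' every parcel by ordinary least squares (intercept + global regressor),
#' then re-standardizes each residual column to zero mean and unit variance.
#' The residuals are exactly orthogonal to the global mean.
#'
#' @param ts A `parcel_ts` scan.
#' @return A `parcel_ts` with `variant = "GSR"`.
#' @export
global_signal_regress <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  X <- ts$data
  if (nrow(X) < 3L) stop("need at least 3 time points for GSR")
  g <- rowMeans(X)
  gc <- g - mean(g)
  ss <- sum(gc^2)
  if (ss < 1e-12) stop("degenerate input: global signal has zero variance")
  Xc <- sweep(X, 2L, colMeans(X))
  beta <- as.vector(crossprod(gc, Xc)) / ss
  R <- Xc - gc %o% beta
  sds <- sqrt(colSums(R^2) / (nrow(R) - 1L))
  if (any(sds < 1e-10))
    stop("degenerate residuals after GSR (parcels collinear with the global ",
         "signal): ", paste(colnames(X)[sds < 1e-10], collapse = ", "))
  R <- scale(R)
  attr(R, "scaled:center") <- NULL
  attr(R, "scaled:scale") <- NULL
  colnames(R) <- colnames(X)
  out <- ts
  out$data <- R
  out$variant <- "GSR"
  out
}

#' Pearson functional connectivity matrix
#'
#' Sample Pearson correlation between every pair of parcel time courses,
#' with the diagonal set to exactly 1.
#'
#' @param ts A `parcel_ts` scan.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (P x P symmetric matrix) and `variant` ("GSR" or "noGSR").
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  X <- ts$data
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12))
    stop("constant parcel time course(s): ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  C <- stats::cor(X)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(list(values = C, variant = ts$variant), class = "connectivity_matrix")
}

as_conn_values <- function(cm) {
  if (inherits(cm, "connectivity_matrix")) cm$values
  else if (is.matrix(cm)) cm
  else stop("expected a `connectivity_matrix` or a square matrix")
}

conn_variant <- function(cm, default = "noGSR") {
  if (inherits(cm, "connectivity_matrix")) cm$variant else default
}

# population (divide-by-N) standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

feature_block <- function(values, family) {
  structure(list(names = names(values), values = values, family = family),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat("Feature block '", x$family, "': ", length(x$values), " features\n",
      sep = "")
  print(utils::head(x$values, 8L))
  if (length(x$values) > 8L) cat("...\n")
  invisible(x)
}

#' Connectivity-profile features (58 per variant)
#'
#' Mean and population standard deviation of the off-diagonal connectivity
#' values over 29 scopes: the whole matrix, each of the 7 networks, and each
#' of the 21 between-network pairs. Every unordered parcel pair is counted
#' once and the diagonal is excluded. Order: the 29 means (WB, networks,
#' pairs), then the 29 SDs.
#'
#' @param cm A `connectivity_matrix` (or plain symmetric matrix).
#' @param partition A `network_partition` matching the matrix dimension.
#' @return A `feature_block` of 58 named features, family `conn_<variant>`.
#' @export
connectivity_features <- function(cm, partition) {
  partition <- as_partition(partition)
  V <- as_conn_values(cm)
  if (nrow(V) != partition$parcel_count)
    stop("matrix dimension does not match partition")
  family <- paste0("conn_", conn_variant(cm))
  ps <- pair_scope_ids(partition)
  vals <- V[cbind(ps$i, ps$j)]
  scopes <- scope_labels(partition$networks)
  n_scope <- tabulate(ps$scope, nbins = 28L)
  few <- scopes[-1L][n_scope < 2L]
  if (length(few))
    stop("scope(s) with fewer than 2 parcel pairs (SD undefined): ",
         paste(few, collapse = ", "))
  scope_f <- factor(ps$scope, levels = seq_len(28L))
  means <- as.vector(tapply(vals, scope_f, mean))
  sds <- as.vector(tapply(vals, scope_f, pop_sd))
  m_all <- c(mean(vals), means)
  s_all <- c(pop_sd(vals), sds)
  out <- c(m_all, s_all)
  names(out) <- c(paste0(family, ":mean:", scopes), paste0(family, ":sd:", scopes))
  feature_block(out, family)
}
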