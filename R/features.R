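#' Canonical 324-feature name vector
#'
#' The fixed, documented feature order used everywhere in the package:
#' 58 noGSR connectivity, 58 GSR connectivity, 74 noGSR graph, 74 GSR
#' graph, 60 gradient features.
#'
#' @param partition A `network_partition` (only the network names matter).
#' @return Character vector of length 324.
#' @export
feature_names <- function(partition = make_partition(28)) {
  partition <- as_partition(partition)
  nets <- partition$networks
  scopes <- scope_labels(nets)
  conn <- function(fam) paste0(fam, ":", rep(c("mean", "sd"), each = 29L),
                               ":", scopes)
  graph <- function(fam) c(
    paste0(fam, ":eff:", scopes), paste0(fam, ":eff_intra:", nets),
    paste0(fam, ":clust:", c("WB", nets)), paste0(fam, ":clust_intra:", nets),
    paste0(fam, ":Q:", c("WB", nets)),
    paste0(fam, ":part:", c("WB", nets)), paste0(fam, ":part_intra:", nets))
  pr <- network_pairs(nets)
  grad <- c(paste0("gradient:range:", rep(c("WB", nets), each = 3L),
                   ":g", rep(1:3, 8L)),
            paste0("gradient:disp:", c("WB", nets)),
            paste0("gradient:ecc:", nets),
            paste0("gradient:dist:", pr$a, "-", pr$b))
  c(conn("conn_noGSR"), conn("conn_GSR"),
    graph("graph_noGSR"), graph("graph_GSR"), grad)
}

#' Family tag of each canonical feature
#' @inheritParams feature_names
#' @return Character vector of length 324 over
#'   `{conn_noGSR, conn_GSR, graph_noGSR, graph_GSR, gradient}`.
#' @export
feature_families <- function(partition = make_partition(28)) {
  sub("^([^:]+):.*$", "\\1", feature_names(partition))
}

#' Extract the full 324-feature table for a cohort
#'
#' Runs the complete feature-engineering pipeline on every scan of a
#' cohort: Pearson connectivity with and without global signal regression,
#' connectivity-profile features (58 x 2), graph-theoretic features on
#' density-thresholded binary graphs (74 x 2), and cortical-gradient
#' features (60) from diffusion-map embeddings of the GSR matrix aligned by
#' Procrustes rotation to a reference. If no reference is supplied, a group
#' template is built from the cohort's baseline scans
#' (see [gradient_reference()]).
#'
#' @param cohort A `cohort` (from [simulate_condition()] or [read_cohort()]).
#' @param density Edge density for graph binarization and row-wise gradient
#'   sparsification (default 0.1).
#' @param gradient_ref Optional P x 3 reference matrix; default NULL builds
#'   the group baseline template.
#' @return An object of class `brainstate_features`: list with `x`
#'   (scans x 324 matrix, canonical column order), `subject_id`, `state`,
#'   `condition`, `families` (column family tags), `partition` and
#'   `gradient_ref` (the reference actually used).
#' @export
extract_features <- function(cohort, density = 0.1, gradient_ref = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  partition <- cohort$partition
  scans <- cohort$scans
  n <- length(scans)
  cms_no <- vector("list", n)
  cms_gsr <- vector("list", n)
  for (i in seq_len(n)) {
    cms_no[[i]] <- pearson_connectivity(scans[[i]])
    cms_gsr[[i]] <- pearson_connectivity(global_signal_regress(scans[[i]]))
  }
  embeds <- lapply(cms_gsr, function(cm)
    diffusion_embedding(cosine_affinity(rowwise_sparsify(cm, density))))
  if (is.null(gradient_ref)) {
    base_idx <- which(vapply(scans, function(s) s$state == "baseline", logical(1)))
    if (!length(base_idx)) base_idx <- seq_len(n)
    gradient_ref <- gradient_reference(embeds[base_idx])
  }
  nm <- feature_names(partition)
  X <- matrix(NA_real_, n, length(nm), dimnames = list(
    vapply(scans, function(s) paste0(s$subject_id, "_", s$state), character(1)),
    nm))
  for (i in seq_len(n)) {
    aligned <- procrustes_align(embeds[[i]], gradient_ref, "group_baseline")
    vals <- c(connectivity_features(cms_no[[i]], partition)$values,
              connectivity_features(cms_gsr[[i]], partition)$values,
              graph_features(cms_no[[i]], partition, density)$values,
              graph_features(cms_gsr[[i]], partition, density)$values,
              gradient_features(aligned, partition)$values)
    stopifnot(identical(names(vals), nm))
    X[i, ] <- vals
  }
  structure(
    list(x = X,
         subject_id = vapply(scans, function(s) s$subject_id, character(1)),
         state = vapply(scans, function(s) s$state, character(1)),
         condition = cohort$condition,
         families = feature_families(partition),
         partition = partition,
         gradient_ref = gradient_ref),
    class = "brainstate_features")
}

#' @export
print.brainstate_features <- function(x, ...) {
  cat("Brain-state features '", x$condition, "': ", nrow(x$x), " scans x ",
      ncol(x$x), " features\n", sep = "")
  print(table(x$families)[unique(x$families)])
  invisible(x)
}
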