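#' Canonical network names
#'
#' The seven canonical resting-state networks, in the fixed order used for
#' every feature name and scope in this package: visual (VIS), somatomotor
#' (SMN), dorsal attention (DAN), ventral attention (VAN), limbic (LIM),
#' frontoparietal (FPN) and default-mode (DMN).
#'
#' @return Character vector of length 7.
#' @export
canonical_networks <- function() {
  c("VIS", "SMN", "DAN", "VAN", "LIM", "FPN", "DMN")
}

#' Build a parcel-to-network partition
#'
#' Assigns `parcel_count` parcels to seven networks as contiguous blocks in
#' the declared network order. With `sizes = NULL` the parcels are split
#' near-equally across the canonical networks (earlier networks receive the
#' remainder).
#'
#' @param parcel_count Total number of parcels (positive integer).
#' @param sizes Named integer vector giving the number of parcels per
#'   network. Must cover exactly 7 uniquely named networks, each with at
#'   least 2 parcels, and sum to `parcel_count`.
#' @return An object of class `network_partition`: a list with elements
#'   `parcel_count`, `labels` (one network name per parcel), `networks`
#'   (the 7 names in declared order) and `parcel_names`.
#' @examples
#' p <- make_partition(28)
#' table(p$labels)
#' @export
make_partition <- function(parcel_count, sizes = NULL) {
  parcel_count <- as.integer(parcel_count)
  if (length(parcel_count) != 1L || is.na(parcel_count) || parcel_count < 14L)
    stop("`parcel_count` must be a single integer >= 14 (2 parcels per network)")
  if (is.null(sizes)) {
    nets <- canonical_networks()
    base <- parcel_count %/% 7L
    extra <- parcel_count %% 7L
    sizes <- stats::setNames(rep(base, 7L) + as.integer(seq_len(7L) <= extra), nets)
  }
  nets <- names(sizes)
  if (is.null(nets) || length(nets) != 7L || anyDuplicated(nets))
    stop("`sizes` must name exactly 7 unique networks")
  sizes <- as.integer(sizes)
  small <- nets[sizes < 2L]
  if (length(small))
    stop("every network needs >= 2 parcels; offending network(s): ",
         paste(small, collapse = ", "))
  if (sum(sizes) != parcel_count)
    stop("network sizes sum to ", sum(sizes), " but `parcel_count` is ",
         parcel_count, " (networks: ", paste(nets, collapse = ", "), ")")
  labels <- rep(nets, times = sizes)
  structure(
    list(parcel_count = parcel_count,
         labels = labels,
         networks = nets,
         parcel_names = sprintf("P%03d", seq_len(parcel_count))),
    class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("Network partition:", x$parcel_count, "parcels, 7 networks\n")
  print(table(factor(x$labels, levels = x$networks)))
  invisible(x)
}

# Unordered network pairs in canonical enumeration order (21 for 7 networks).
network_pairs <- function(networks) {
  idx <- utils::combn(seq_along(networks), 2L)
  data.frame(a = networks[idx[1L, ]], b = networks[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# Scope labels shared by connectivity/efficiency/gradient features:
# whole brain, 7 within-network, 21 between-network pairs.
scope_labels <- function(networks) {
  pr <- network_pairs(networks)
  c("WB", networks, paste0(pr$a, "-", pr$b))
}

# For every unordered parcel pair (upper triangle, i < j), the scope it
# falls in: 1 = first network, ..., 7, then the 21 pairs in canonical
# order offset by 7. Returns list(i, j, scope_id) with scope ids indexing
# scope_labels(networks)[-1].
pair_scope_ids <- function(partition) {
  P <- partition$parcel_count
  lab <- match(partition$labels, partition$networks)
  iu <- which(upper.tri(diag(P)), arr.ind = TRUE)
  a <- pmin(lab[iu[, 1L]], lab[iu[, 2L]])
  b <- pmax(lab[iu[, 1L]], lab[iu[, 2L]])
  # pair (a < b) -> canonical combn index
  pair_id <- (a - 1L) * 7L - (a * (a - 1L)) %/% 2L + (b - a)
  scope <- ifelse(a == b, a, 7L + pair_id)
  list(i = iu[, 1L], j = iu[, 2L], scope = scope)
}

as_partition <- function(partition) {
  if (!inherits(partition, "network_partition"))
    stop("`partition` must be a `network_partition` (see make_partition())")
  partition
}
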