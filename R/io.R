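#' Write a cohort to disk as TSV scans plus a JSON sidecar
#'
#' One tab-separated file per scan (`<subject>_<state>.tsv`, T rows x P
#' columns, header = parcel names) and `cohort.json` describing the
#' parcel-to-network partition, subject pairing, state labels, condition
#' and seed.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(cohort$scans))
  for (i in seq_along(cohort$scans)) {
    s <- cohort$scans[[i]]
    files[i] <- paste0(s$subject_id, "_", s$state, ".tsv")
    utils::write.table(s$data, file.path(dir, files[i]), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  meta <- list(
    condition = cohort$condition,
    seed = cohort$seed,
    partition = list(parcel_count = cohort$partition$parcel_count,
                     networks = cohort$partition$networks,
                     labels = cohort$partition$labels,
                     parcel_names = cohort$partition$parcel_names),
    scans = data.frame(
      file = files,
      subject_id = vapply(cohort$scans, function(s) s$subject_id, character(1)),
      state = vapply(cohort$scans, function(s) s$state, character(1)),
      stringsAsFactors = FALSE))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing scan TSVs and `cohort.json`.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  part <- structure(
    list(parcel_count = as.integer(meta$partition$parcel_count),
         labels = meta$partition$labels,
         networks = meta$partition$networks,
         parcel_names = meta$partition$parcel_names),
    class = "network_partition")
  scans <- vector("list", nrow(meta$scans))
  for (i in seq_len(nrow(meta$scans))) {
    X <- as.matrix(utils::read.table(file.path(dir, meta$scans$file[i]),
                                     header = TRUE, sep = "\t",
                                     check.names = FALSE))
    scans[[i]] <- structure(
      list(data = X, subject_id = meta$scans$subject_id[i],
           state = meta$scans$state[i], condition = meta$condition,
           t_points = nrow(X), variant = "noGSR"),
      class = "parcel_ts")
  }
  sids <- unique(meta$scans$subject_id)
  pairing <- stats::setNames(lapply(sids, function(sid) {
    c(baseline = which(meta$scans$subject_id == sid &
                         meta$scans$state == "baseline")[1L],
      atypical = which(meta$scans$subject_id == sid &
                         meta$scans$state == "atypical")[1L])
  }), sids)
  structure(
    list(scans = scans, partition = part, pairing = pairing,
         condition = meta$condition, seed = meta$seed),
    class = "cohort")
}

#' Write an extracted feature table
#'
#' `features.tsv` holds one row per scan (`subject_id`, `state` plus the
#' 324 named feature columns); `features.json` records provenance
#' (condition, families, partition networks).
#'
#' @param features A `brainstate_features` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_features <- function(features, dir) {
  stopifnot(inherits(features, "brainstate_features"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(subject_id = features$subject_id, state = features$state,
                   features$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(condition = features$condition,
         families = features$families,
         networks = features$partition$networks,
         labels = features$partition$labels,
         parcel_count = features$partition$parcel_count,
         gradient_ref = features$gradient_ref),
    file.path(dir, "features.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a feature table written by [write_features()]
#' @param dir Directory containing `features.tsv` and `features.json`.
#' @return A `brainstate_features` object.
#' @export
read_features <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "features.json"),
                              simplifyVector = TRUE)
  df <- utils::read.table(file.path(dir, "features.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  part <- structure(
    list(parcel_count = as.integer(meta$parcel_count),
         labels = meta$labels, networks = meta$networks,
         parcel_names = sprintf("P%03d", seq_len(meta$parcel_count))),
    class = "network_partition")
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(X) <- paste0(df$subject_id, "_", df$state)
  structure(
    list(x = X, subject_id = df$subject_id, state = df$state,
         condition = meta$condition, families = meta$families,
         partition = part,
         gradient_ref = if (!is.null(meta$gradient_ref))
           matrix(unlist(meta$gradient_ref), ncol = 3L) else NULL),
    class = "brainstate_features")
}
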