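#' State parameters for the synthetic cohort generator
#'
#' Parameterizes the factor model that generates parcel time series for one
#' brain state: each parcel carries a shared global factor (weight
#' `global_amp`), its network's factor (weight `net_amp`, the 7 network
#' factors being correlated according to `coupling`) and white measurement
#' noise (`noise_sd`). All factors and noise are standard normal and white in
#' time.
#'
#' The model-implied covariance between parcels p (network a) and q
#' (network b), p != q, is
#' `global_amp^2 + net_amp[a] * net_amp[b] * coupling[a, b]`, and each
#' parcel's variance is `global_amp^2 + net_amp^2 + noise_sd^2`; see
#' [implied_correlation()].
#'
#' @param global_amp Nonnegative weight of the shared global signal.
#' @param net_amp Nonnegative within-network factor weight; a scalar
#'   (recycled) or a named vector over `networks`.
#' @param coupling Inter-network factor correlation: a symmetric 7 x 7
#'   matrix with unit diagonal and entries in `[-1, 1]`, or a scalar used for
#'   all off-diagonal entries. Must be positive semidefinite.
#' @param noise_sd Positive standard deviation of parcel-specific noise.
#' @param networks Network names (default canonical 7).
#' @param perturbation_tags List of named planted effects (see
#'   [planted_effects()]); purely descriptive metadata.
#' @return An object of class `state_params`.
#' @seealso [simulate_scan()], [simulate_condition()], [planted_effects()]
#' @export
state_params <- function(global_amp = 0.4, net_amp = 0.6, coupling = 0.1,
                         noise_sd = 1, networks = canonical_networks(),
                         perturbation_tags = list()) {
  k <- length(networks)
  if (k != 7L) stop("exactly 7 networks expected")
  if (length(global_amp) != 1L || global_amp < 0)
    stop("`global_amp` must be a single nonnegative number")
  if (length(net_amp) == 1L) net_amp <- stats::setNames(rep(net_amp, k), networks)
  if (is.null(names(net_amp))) names(net_amp) <- networks
  net_amp <- net_amp[networks]
  if (anyNA(net_amp) || any(net_amp < 0))
    stop("`net_amp` must be nonnegative and cover all networks")
  if (length(coupling) == 1L) {
    coupling <- matrix(coupling, k, k)
    diag(coupling) <- 1
  }
  dimnames(coupling) <- list(networks, networks)
  if (length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single nonnegative number")
  p <- structure(
    list(global_amp = global_amp, net_amp = net_amp, coupling = coupling,
         noise_sd = noise_sd, networks = networks,
         perturbation_tags = perturbation_tags),
    class = "state_params")
  validate_state_params(p)
  p
}

validate_state_params <- function(p) {
  cp <- p$coupling
  if (!isSymmetric(unname(cp), tol = 1e-8))
    stop("`coupling` must be symmetric")
  if (max(abs(diag(cp) - 1)) > 1e-8)
    stop("`coupling` must have unit diagonal")
  if (any(abs(cp) > 1 + 1e-8))
    stop("`coupling` entries must lie in [-1, 1]")
  ev <- eigen((cp + t(cp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`coupling` is not positive semidefinite (min eigenvalue ",
         format(min(ev)), "); implied parcel covariance would be invalid")
  invisible(p)
}

# Symmetric PSD square root via eigendecomposition (deterministic).
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Shift the coupling between two networks
#'
#' Convenience constructor of a perturbed [state_params()]: adds `delta` to
#' the factor correlation between networks `a` and `b` and records the
#' planted effect in `perturbation_tags`.
#'
#' @param params A `state_params` object.
#' @param a,b Network names.
#' @param delta Additive shift of the coupling entry.
#' @return A new `state_params` with the shifted (still validated) coupling.
#' @export
with_coupling_shift <- function(params, a, b, delta) {
  cp <- params$coupling
  stopifnot(a %in% params$networks, b %in% params$networks, a != b)
  cp[a, b] <- cp[a, b] + delta
  cp[b, a] <- cp[a, b]
  state_params(params$global_amp, params$net_amp, cp, params$noise_sd,
               params$networks,
               c(params$perturbation_tags,
                 list(list(type = "coupling", networks = c(a, b), delta = delta))))
}

#' @rdname with_coupling_shift
#' @param value New amplitude value.
#' @export
with_global_amp <- function(params, value) {
  state_params(value, params$net_amp, params$coupling, params$noise_sd,
               params$networks,
               c(params$perturbation_tags, list(list(type = "global_amp", value = value))))
}

#' @rdname with_coupling_shift
#' @param network Network whose factor weight is replaced.
#' @export
with_net_amp <- function(params, network, value) {
  stopifnot(network %in% params$networks)
  na <- params$net_amp
  na[network] <- value
  state_params(params$global_amp, na, params$coupling, params$noise_sd,
               params$networks,
               c(params$perturbation_tags,
                 list(list(type = "net_amp", network = network, value = value))))
}

#' Model-implied parcel correlation matrix
#'
#' Closed-form Pearson correlation between parcels under the factor model of
#' [state_params()]; useful as an analytic oracle for the generator.
#'
#' @param params A `state_params` object.
#' @param partition A `network_partition`.
#' @return P x P correlation matrix (unit diagonal).
#' @export
implied_correlation <- function(params, partition) {
  partition <- as_partition(partition)
  lab <- match(partition$labels, params$networks)
  if (anyNA(lab)) stop("partition networks do not match `params$networks`")
  amp <- unname(params$net_amp)[lab]
  cov_net <- (amp %o% amp) * params$coupling[lab, lab]
  S <- params$global_amp^2 + cov_net
  v <- params$global_amp^2 + amp^2 + params$noise_sd^2
  R <- S / sqrt(v %o% v)
  diag(R) <- 1
  dimnames(R) <- list(partition$parcel_names, partition$parcel_names)
  R
}

#' Simulate one parcellated scan
#'
#' Draws a T x P parcel time-series matrix from the factor model of
#' [state_params()] and standardizes every column to zero mean and unit
#' variance, emulating a preprocessed, z-scored parcellated BOLD scan.
#' Reproducible: the same `(params, partition, t_points, seed)` yields
#' bit-identical output.
#'
#' @param params A `state_params` object.
#' @param partition A `network_partition`.
#' @param t_points Number of time points (>= 30, for correlation stability).
#' @param seed Integer seed.
#' @param subject_id,state,condition Metadata carried on the scan.
#' @return An object of class `parcel_ts`: list with `data` (T x P matrix,
#'   columns named by parcel), `subject_id`, `state`, `condition`,
#'   `t_points` and `variant` ("noGSR").
#' @export
simulate_scan <- function(params, partition, t_points, seed,
                          subject_id = "sim", state = "baseline",
                          condition = "synthetic") {
  validate_state_params(params)
  partition <- as_partition(partition)
  t_points <- as.integer(t_points)
  if (t_points < 30L) stop("`t_points` must be >= 30")
  if (params$global_amp == 0 && all(params$net_amp == 0) && params$noise_sd == 0)
    stop("degenerate model: all amplitudes zero")
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  P <- partition$parcel_count
  k <- length(params$networks)
  g <- stats::rnorm(t_points)
  Z <- matrix(stats::rnorm(t_points * k), t_points, k)
  U <- Z %*% psd_sqrt(params$coupling)
  E <- matrix(stats::rnorm(t_points * P), t_points, P)
  lab <- match(partition$labels, params$networks)
  amp <- unname(params$net_amp)[lab]
  X <- params$global_amp * g %o% rep(1, P) +
    U[, lab, drop = FALSE] * rep(amp, each = t_points) +
    params$noise_sd * E
  sds <- apply(X, 2L, stats::sd)
  if (any(sds < 1e-12))
    stop("degenerate scan: parcel(s) with zero variance: ",
         paste(partition$parcel_names[sds < 1e-12], collapse = ", "))
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- partition$parcel_names
  structure(
    list(data = X, subject_id = subject_id, state = state,
         condition = condition, t_points = t_points, variant = "noGSR"),
    class = "parcel_ts")
}

#' Simulate a paired baseline/atypical cohort
#'
#' Generates `n_subjects` subjects, each contributing one baseline and one
#' atypical scan (within-subject paired design). Subject heterogeneity is
#' modelled as multiplicative log-normal jitter (sdlog = 0.1) on the global
#' and network amplitudes, shared between a subject's two scans so the pair
#' shares its nuisance structure.
#'
#' @param baseline,atypical `state_params` for the two states.
#' @param partition A `network_partition`.
#' @param n_subjects Number of subjects (>= 4, so 3 inner CV folds can be
#'   formed downstream).
#' @param t_points Time points per scan.
#' @param seed Integer seed governing all randomness.
#' @param condition Condition name carried on every scan.
#' @return An object of class `cohort`: list with `scans` (list of
#'   `parcel_ts`), `partition`, `pairing` (subject -> scan indices),
#'   `condition`, `seed`, and the two parameter sets.
#' @export
simulate_condition <- function(baseline, atypical, partition, n_subjects,
                               t_points, seed, condition = "synthetic") {
  validate_state_params(baseline)
  validate_state_params(atypical)
  partition <- as_partition(partition)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L)
    stop("`n_subjects` must be >= 4 (3 inner folds cannot be formed otherwise)")
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  jit_g <- stats::rlnorm(n_subjects, 0, 0.1)
  jit_net <- matrix(stats::rlnorm(n_subjects * 7L, 0, 0.1), n_subjects, 7L)
  scan_seeds <- sample.int(.Machine$integer.max, 2L * n_subjects)
  scans <- vector("list", 2L * n_subjects)
  pairing <- stats::setNames(vector("list", n_subjects),
                             sprintf("S%03d", seq_len(n_subjects)))
  idx <- 0L
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    pair <- integer(2L)
    for (s in 1:2) {
      par0 <- if (s == 1L) baseline else atypical
      par_i <- par0
      par_i$global_amp <- par0$global_amp * jit_g[i]
      par_i$net_amp <- par0$net_amp * jit_net[i, ]
      idx <- idx + 1L
      scans[[idx]] <- simulate_scan(
        par_i, partition, t_points, scan_seeds[idx], subject_id = sid,
        state = c("baseline", "atypical")[s], condition = condition)
      pair[s] <- idx
    }
    pairing[[sid]] <- c(baseline = pair[1L], atypical = pair[2L])
  }
  structure(
    list(scans = scans, partition = partition, pairing = pairing,
         condition = condition, seed = as.integer(seed),
         baseline_params = baseline, atypical_params = atypical),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort '", x$condition, "': ", length(x$pairing),
      " subjects, ", length(x$scans), " scans (paired baseline/atypical), ",
      x$partition$parcel_count, " parcels, T = ", x$scans[[1L]]$t_points,
      "\n", sep = "")
  invisible(x)
}

#' Feature names expected to discriminate for planted effects
#'
#' Maps planted generator perturbations to the canonical names of the
#' features they are expected to move, the ground truth for
#' importance-recovery tests. Known tags: `coupling` (networks a, b),
#' `global_amp`, `net_amp` (network), `noise_sd`.
#'
#' @param spec A `state_params` (its `perturbation_tags` are used) or a list
#'   of tag lists, each with a `type` field.
#' @return Character vector of canonical feature names (empty if no tags).
#' @export
planted_effects <- function(spec) {
  tags <- if (inherits(spec, "state_params")) spec$perturbation_tags else spec
  if (!length(tags)) return(character(0))
  nets <- canonical_networks()
  out <- character(0)
  for (tg in tags) {
    if (is.null(tg$type)) stop("planted-effect tag without `type`")
    out <- c(out, switch(
      tg$type,
      coupling = {
        ab <- tg$networks
        ab <- ab[order(match(ab, nets))]
        pair <- paste0(ab[1L], "-", ab[2L])
        c(paste0("conn_noGSR:mean:", pair), paste0("conn_GSR:mean:", pair))
      },
      global_amp = "conn_noGSR:mean:WB",
      net_amp = c(paste0("conn_noGSR:mean:", tg$network),
                  paste0("conn_GSR:mean:", tg$network)),
      noise_sd = c("conn_noGSR:mean:WB", "conn_noGSR:sd:WB"),
      stop("unknown planted-effect tag: ", tg$type)))
  }
  unique(out)
}
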