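#' HMM parameters for a copy-number cluster
#'
#' The cluster model is a hidden Markov chain over K discrete copy-number
#' states (default K = 6, state values 0.1, 1.5, 2, 3, 4, 5 covering
#' homozygous deletion through high-level amplification). Transitions
#' between adjacent segments are exchangeable: probability `p_same` of
#' staying in the same state and `(1 - p_same) / (K - 1)` for each other
#' state. Every sample assigned to the cluster emits its observed segment
#' mean independently from a lognormal distribution whose underlying
#' normal has mean `log(state value)` and standard deviation `sigma`, so
#' the state's copy number is the median of the emission distribution.
#'
#' @param states strictly increasing positive numeric vector of hidden
#'   copy-number state values.
#' @param p_same probability, in (0, 1), of remaining in the same state
#'   between adjacent segments.
#' @param sigma standard deviation (log scale) of the emission
#'   distribution; must be positive.
#' @param initial initial state distribution; defaults to uniform.
#' @return Object of class `hmm_params` with elements `states`, `K`,
#'   `p_same`, `p_diff`, `sigma`, `initial`.
#' @examples
#' hmm_params(p_same = 0.56, sigma = 0.3)
#' @export
hmm_params <- function(states = c(0.1, 1.5, 2, 3, 4, 5),
                       p_same = 0.56, sigma = 0.3,
                       initial = NULL) {
  if (any(states <= 0) || any(diff(states) <= 0))
    stop("'states' must be strictly increasing and positive")
  K <- length(states)
  if (p_same <= 0 || p_same >= 1) stop("'p_same' must be in (0, 1)")
  if (sigma <= 0) stop("'sigma' must be positive")
  if (is.null(initial)) initial <- rep(1 / K, K)
  if (length(initial) != K || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-8)
    stop("'initial' must be a length-K probability vector")
  structure(list(states = states, K = K, p_same = p_same,
                 p_diff = (1 - p_same) / (K - 1), sigma = sigma,
                 initial = initial / sum(initial)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("Copy-number HMM: K =", x$K, "states (",
      paste(x$states, collapse = ", "), ")\n")
  cat("  p_same =", format(x$p_same, digits = 4),
      " p_diff =", format(x$p_diff, digits = 4),
      " sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' Lognormal emission log-density
#'
#' Log-density of observing linear copy number `y` from a hidden state with
#' copy-number value `state_value`: the lognormal whose underlying normal
#' has mean `log(state_value)` and standard deviation `sigma`.
#'
#' @param y observed mean copy number(s); must be positive.
#' @param state_value hidden state copy-number value (positive).
#' @param sigma log-scale standard deviation (positive).
#' @return numeric vector of log-densities.
#' @export
emission_logdensity <- function(y, state_value, sigma) {
  if (any(y <= 0)) stop("observations must be positive linear copy numbers")
  if (any(state_value <= 0) || sigma <= 0)
    stop("state_value and sigma must be positive")
  stats::dlnorm(y, meanlog = log(state_value), sdlog = sigma, log = TRUE)
}

#' Estimate the emission standard deviation from data
#'
#' For each segment, the standard deviation of log copy number across
#' samples is computed; the estimate is the mean over segments, floored at
#' `floor` to avoid degenerate zero-variance emissions. Because the
#' computation is on the log scale it is invariant to rescaling all values
#' by a constant.
#'
#' @param m a [cn_matrix()] with at least 2 samples.
#' @param floor minimum returned value (default 0.05).
#' @return positive scalar sigma estimate.
#' @export
estimate_emission_sd <- function(m, floor = 0.05) {
  stopifnot(inherits(m, "cn_matrix"))
  if (nrow(m$values) < 2)
    stop("need at least 2 samples to estimate sigma; supply it explicitly")
  sds <- apply(log(m$values), 2, stats::sd)
  max(mean(sds), floor)
}

#' Estimate the same-state transition probability from data
#'
#' Each cell is discretized to the nearest hidden state value (ties at a
#' midpoint go to the lower state). Over all samples and all pairs of
#' adjacent segments within a chromosome, same-state and different-state
#' transitions are counted with add-one smoothing on the two categories,
#' giving `p_same`; the remaining mass is shared uniformly across the
#' K - 1 other states, `p_diff = (1 - p_same) / (K - 1)`.
#'
#' @param m a [cn_matrix()] with at least 2 segments.
#' @param states hidden state values.
#' @return list with elements `p_same` and `p_diff`.
#' @export
estimate_transition_probs <- function(m, states = c(0.1, 1.5, 2, 3, 4, 5)) {
  stopifnot(inherits(m, "cn_matrix"))
  if (ncol(m$values) < 2) stop("need at least 2 segments")
  K <- length(states)
  disc <- discretize_to_states(m$values, states)
  runs <- chromosome_runs(m$grid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  n_same <- 0L; n_total <- 0L
  for (r in seq_along(starts)) {
    if (runs$lengths[r] < 2) next
    idx <- starts[r]:ends[r]
    a <- disc[, idx[-length(idx)], drop = FALSE]
    b <- disc[, idx[-1], drop = FALSE]
    n_same <- n_same + sum(a == b)
    n_total <- n_total + length(a)
  }
  p_same <- (n_same + 1) / (n_total + 2)
  list(p_same = p_same, p_diff = (1 - p_same) / (K - 1))
}

# Map values to nearest state index; ties at midpoints go to the lower state.
discretize_to_states <- function(x, states) {
  mids <- (states[-1] + states[-length(states)]) / 2
  idx <- findInterval(x, mids, left.open = TRUE) + 1L
  array(idx, dim = dim(x))
}

# Per-sample emission log-density array, K x T x n. Precomputed once per
# matrix so that group emissions during the search are just sums over the
# member slices.
emission_array <- function(m, params) {
  y <- t(m$values)                       # T x n
  K <- params$K
  out <- array(NA_real_, c(K, ncol(m$values), nrow(m$values)))
  for (k in seq_len(K))
    out[k, , ] <- stats::dlnorm(y, meanlog = log(params$states[k]),
                                sdlog = params$sigma, log = TRUE)
  out
}

# Viterbi on one chromosome run given the K x T joint emission log-density.
# The exchangeable transition structure (log p_same on the diagonal,
# log p_diff elsewhere) admits an O(K) update per segment: the best
# predecessor of state k is either k itself (stay) or the argmax over the
# other states (move), found with a top-2 trick.
viterbi_run <- function(emis, log_init, log_same, log_diff) {
  K <- nrow(emis); T_n <- ncol(emis)
  back <- matrix(0L, K, T_n)
  d <- log_init + emis[, 1]
  if (T_n > 1) {
    for (t in 2:T_n) {
      o <- order(d, decreasing = TRUE)
      i1 <- o[1]; i2 <- o[2]
      stay <- d + log_same
      move_val <- d[i1] + log_diff
      move_from <- rep(i1, K)
      move_val <- rep(move_val, K)
      move_val[i1] <- d[i2] + log_diff
      move_from[i1] <- i2
      take_stay <- stay >= move_val
      d <- ifelse(take_stay, stay, move_val) + emis[, t]
      back[, t] <- ifelse(take_stay, seq_len(K), move_from)
    }
  }
  path <- integer(T_n)
  path[T_n] <- which.max(d)
  if (T_n > 1) for (t in (T_n - 1):1) path[t] <- back[path[t + 1], t + 1]
  list(delta = max(d), path = path)
}

#' Viterbi delta log-likelihood of a cluster
#'
#' Fits the cluster HMM to a set of samples by Viterbi decoding: a single
#' hidden copy-number chain is shared by all member samples, and the joint
#' emission log-density at segment t in state k is the sum over members of
#' the lognormal emission log-density of each member's observed value. The
#' returned `delta` is the log-probability of the best hidden path
#' (initial + transitions + all member emissions); the chain restarts from
#' the initial distribution at each chromosome boundary.
#'
#' @param m a [cn_matrix()].
#' @param member_rows integer (or logical) index of the member samples.
#' @param params an [hmm_params()].
#' @param emis_array optional precomputed [emission array][cn_matrix]
#'   (internal use, K x T x n) to avoid recomputing emissions.
#' @return list with `delta` (the Viterbi log-likelihood, the cluster's
#'   Delta value) and `path` (length-T vector of decoded state indices).
#' @export
cluster_delta <- function(m, member_rows, params, emis_array = NULL) {
  stopifnot(inherits(m, "cn_matrix"), inherits(params, "hmm_params"))
  if (is.logical(member_rows)) member_rows <- which(member_rows)
  if (length(member_rows) == 0) stop("cluster has no member samples")
  if (is.null(emis_array)) emis_array <- emission_array(m, params)
  emis <- if (length(member_rows) == 1L)
    emis_array[, , member_rows]
  else
    rowSums(emis_array[, , member_rows, drop = FALSE], dims = 2)
  if (ncol(m$values) == 1L) emis <- matrix(emis, ncol = 1L)
  log_init <- log(params$initial)
  log_same <- log(params$p_same)
  log_diff <- log(params$p_diff)
  runs <- chromosome_runs(m$grid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  delta <- 0
  path <- integer(ncol(m$values))
  for (r in seq_along(starts)) {
    idx <- starts[r]:ends[r]
    v <- viterbi_run(emis[, idx, drop = FALSE], log_init,
                     log_same, log_diff)
    delta <- delta + v$delta
    path[idx] <- v$path
  }
  list(delta = delta, path = path)
}
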