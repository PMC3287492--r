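#' Search configuration for the HMM clustering optimizer
#'
#' @param G number of groups.
#' @param m_stop number of consecutive non-improving proposals before the
#'   search stops. The default, used when `m_stop = NULL`, is n^2 for n
#'   samples, which is sufficient for the search to converge in practice.
#' @param seed integer seed.
#' @param max_iters safety cap on total proposals; default `50 * m_stop`.
#' @param n_workers reserved for parallel proposal evaluation; results for
#'   a fixed seed are defined by the `n_workers = 1` execution order.
#' @return object of class `search_config`.
#' @export
search_config <- function(G, m_stop = NULL, seed = 1, max_iters = NULL,
                          n_workers = 1) {
  if (!is.null(m_stop) && m_stop < 1) stop("m_stop must be >= 1")
  if (!is.null(max_iters) && !is.null(m_stop) && max_iters < m_stop)
    stop("max_iters must be >= m_stop")
  structure(list(G = as.integer(G), m_stop = m_stop,
                 seed = as.integer(seed), max_iters = max_iters,
                 n_workers = as.integer(n_workers)),
            class = "search_config")
}

#' Default stopping patience for n samples
#'
#' The search stops after `n^2` consecutive proposals that fail to improve
#' the best log-likelihood; e.g. 79 samples give 6241.
#'
#' @param n number of samples.
#' @return integer n^2.
#' @export
default_m_stop <- function(n) as.integer(as.numeric(n)^2)

#' Total mixture log-likelihood of a cluster assignment
#'
#' Sum over groups of the Viterbi delta value of each group's shared
#' hidden chain. Groups are fitted independently, so per-group values are
#' returned alongside the total.
#'
#' @param m a [cn_matrix()].
#' @param a a [cluster_assignment()]; every group must be non-empty.
#' @param params an [hmm_params()].
#' @param emis_array optional precomputed per-sample emission array.
#' @param cache optional environment used to memoize per-group deltas by
#'   member set; safe because groups are scored independently.
#' @return list with `deltas` (length G) and `total` (their sum).
#' @export
total_loglik <- function(m, a, params, emis_array = NULL, cache = NULL) {
  stopifnot(inherits(a, "cluster_assignment"))
  sizes <- group_sizes(a)
  if (any(sizes == 0))
    stop("empty group(s): ", paste(which(sizes == 0), collapse = ", "))
  if (is.null(emis_array)) emis_array <- emission_array(m, params)
  deltas <- vapply(seq_len(a$G), function(g) {
    members <- which(a$labels == g)
    if (!is.null(cache)) {
      key <- paste(members, collapse = ",")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      d <- cluster_delta(m, members, params, emis_array)$delta
      cache[[key]] <- d
      d
    } else {
      cluster_delta(m, members, params, emis_array)$delta
    }
  }, numeric(1))
  list(deltas = deltas, total = sum(deltas))
}

#' Propose a two-sample relabelling move
#'
#' Picks two distinct samples uniformly at random and assigns each a group
#' label drawn uniformly from 1..G. Proposals that would leave a group
#' empty are redrawn (bounded retries), so the returned assignment always
#' has G non-empty groups. The input assignment is not modified.
#'
#' @param a a [cluster_assignment()] with G >= 2 and n >= 2.
#' @param max_retries bound on redraws of empty-group proposals.
#' @return a new [cluster_assignment()] differing from `a` in at most two
#'   positions.
#' @export
propose_move <- function(a, max_retries = 1000) {
  stopifnot(inherits(a, "cluster_assignment"))
  n <- length(a$labels)
  if (a$G < 2) stop("no moves possible with G = 1")
  if (n < 2) stop("need at least 2 samples")
  for (try in seq_len(max_retries)) {
    labels <- a$labels
    pick <- sample.int(n, 2)
    labels[pick] <- sample.int(a$G, 2, replace = TRUE)
    if (all(tabulate(labels, a$G) > 0))
      return(cluster_assignment(labels, a$G))
  }
  stop("could not draw a proposal keeping all groups non-empty")
}

#' HMM-based clustering by stochastic label search
#'
#' Starting from an initial assignment (typically the NMF seed), the
#' search repeatedly perturbs the current best assignment by re-labelling
#' two random samples, accepts a proposal only when it strictly increases
#' the total Viterbi log-likelihood, and stops once `m_stop` consecutive
#' proposals fail to improve (or the `max_iters` safety cap is reached).
#' Because only accepted moves replace the incumbent, the final
#' log-likelihood is never worse than the seed's.
#'
#' @param m a [cn_matrix()].
#' @param params an [hmm_params()].
#' @param cfg a [search_config()].
#' @param init initial [cluster_assignment()] with `cfg$G` non-empty
#'   groups.
#' @return object of class `hmmc_fit`: list with `assignment`, `deltas`,
#'   `total_loglik`, `trace` (data frame of improvement events with
#'   columns `iteration`, `total_loglik`; iteration 0 is the seed),
#'   `iterations_run`, `params`, and `converged` (FALSE only when the
#'   safety cap cut the search short).
#' @examples
#' d <- generate_dataset(sim_config(s = 0.5, seed = 1))
#' p <- fit_hmm_params(d$matrix)
#' fit <- hmmc_search(d$matrix, p, search_config(G = 2, seed = 1),
#'                    nmf_cluster(d$matrix, 2, seed = 1))
#' fit$total_loglik
#' @export
hmmc_search <- function(m, params, cfg, init) {
  stopifnot(inherits(m, "cn_matrix"), inherits(params, "hmm_params"),
            inherits(cfg, "search_config"),
            inherits(init, "cluster_assignment"))
  n <- nrow(m$values)
  if (length(init$labels) != n) stop("init labels do not match matrix rows")
  if (init$G != cfg$G) stop("init has G = ", init$G, ", expected ", cfg$G)
  if (any(group_sizes(init) == 0)) stop("init has empty group(s)")
  m_stop <- if (is.null(cfg$m_stop)) default_m_stop(n) else cfg$m_stop
  max_iters <- if (is.null(cfg$max_iters)) 50L * m_stop else cfg$max_iters
  set.seed(cfg$seed)
  emis_array <- emission_array(m, params)
  cache <- new.env(parent = emptyenv())

  best <- init
  sc <- total_loglik(m, best, params, emis_array, cache)
  best_deltas <- sc$deltas
  best_ll <- sc$total
  trace_it <- 0L
  trace_ll <- best_ll
  no_improve <- 0L
  iter <- 0L

  if (cfg$G >= 2) {
    while (no_improve < m_stop && iter < max_iters) {
      iter <- iter + 1L
      prop <- propose_move(best)
      changed <- unique(c(best$labels[prop$labels != best$labels],
                          prop$labels[prop$labels != best$labels]))
      if (length(changed) == 0) {
        no_improve <- no_improve + 1L
        next
      }
      # only groups touched by the move need rescoring
      new_deltas <- best_deltas
      for (g in changed) {
        members <- which(prop$labels == g)
        key <- paste(members, collapse = ",")
        hit <- cache[[key]]
        if (is.null(hit)) {
          hit <- cluster_delta(m, members, params, emis_array)$delta
          cache[[key]] <- hit
        }
        new_deltas[g] <- hit
      }
      new_ll <- sum(new_deltas)
      if (new_ll > best_ll) {
        best <- prop
        best_deltas <- new_deltas
        best_ll <- new_ll
        trace_it <- c(trace_it, iter)
        trace_ll <- c(trace_ll, new_ll)
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
      }
    }
    if (iter >= max_iters && no_improve < m_stop)
      warning("search stopped at the max_iters safety cap (", max_iters,
              ")")
  } else {
    iter <- m_stop
  }

  structure(list(assignment = best, deltas = best_deltas,
                 total_loglik = best_ll,
                 trace = data.frame(iteration = trace_it,
                                    total_loglik = trace_ll),
                 iterations_run = iter,
                 params = params,
                 converged = !(iter >= max_iters && no_improve < m_stop)),
            class = "hmmc_fit")
}

#' @export
print.hmmc_fit <- function(x, ...) {
  cat("HMMC fit: G =", x$assignment$G, "groups; sizes:",
      paste(group_sizes(x$assignment), collapse = ", "), "\n")
  cat("  total log-likelihood:", format(x$total_loglik, digits = 8),
      " (", nrow(x$trace) - 1, "accepted moves in", x$iterations_run,
      "proposals )\n")
  invisible(x)
}

#' Estimate HMM parameters from a copy-number matrix
#'
#' Convenience wrapper: estimates the emission standard deviation and the
#' same-state transition probability empirically from the data and returns
#' an [hmm_params()] with a uniform initial distribution. Parameters are
#' estimated once from the full matrix and held fixed during the search.
#'
#' @param m a [cn_matrix()].
#' @param states hidden state copy-number values.
#' @param sigma optional explicit sigma (required for single-sample data).
#' @return an [hmm_params()].
#' @export
fit_hmm_params <- function(m, states = c(0.1, 1.5, 2, 3, 4, 5),
                           sigma = NULL) {
  if (is.null(sigma)) sigma <- estimate_emission_sd(m)
  tr <- estimate_transition_probs(m, states)
  hmm_params(states = states, p_same = tr$p_same, sigma = sigma)
}
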