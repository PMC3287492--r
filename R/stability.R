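#' Leave-k-out stability cross-validation of a clustering
#'
#' Assesses how stable a clustering is under perturbation of the sample
#' set. Per repeat, a random `ceiling(holdout_fraction * n)` samples are
#' left out, HMMC (same G, NMF-seeded) re-clusters the remaining samples,
#' and the retained samples' new labels are matched to the reference
#' labels by the best bijective relabelling; retained samples that land in
#' a different subgroup than in the reference count as errors. Repeats in
#' which an entire reference group disappears from the retained set are
#' redrawn (the bijection would be ill-defined). The error rate is total
#' errors over total retained assignments across repeats.
#'
#' @param m a [cn_matrix()].
#' @param reference the full-data [cluster_assignment()] being tested.
#' @param params an [hmm_params()]; if `NULL`, estimated from `m`.
#' @param cfg a [search_config()] template; seeds are derived per repeat.
#' @param n_repeats number of repeats (default 100).
#' @param holdout_fraction fraction left out per repeat, in (0, 0.5)
#'   (default 0.1); must leave out at least one sample.
#' @param seed master seed.
#' @param n_restarts NMF restarts per repeat.
#' @return list with `error_rate` (pooled), `per_repeat_errors` (integer
#'   vector), `per_repeat_retained` (integer vector), and `redrawn`
#'   (number of redrawn subsamples).
#' @export
crossvalidate_stability <- function(m, reference, params = NULL,
                                    cfg = search_config(G = 2),
                                    n_repeats = 100,
                                    holdout_fraction = 0.1, seed = 1,
                                    n_restarts = 5) {
  stopifnot(inherits(m, "cn_matrix"),
            inherits(reference, "cluster_assignment"))
  n <- nrow(m$values)
  if (holdout_fraction <= 0 || holdout_fraction >= 0.5)
    stop("holdout_fraction must be in (0, 0.5)")
  n_out <- ceiling(holdout_fraction * n)
  if (n_out < 1)
    stop("holdout removes no samples; increase holdout_fraction")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (is.null(params)) params <- fit_hmm_params(m)
  G <- reference$G
  errors <- integer(n_repeats)
  retained_n <- integer(n_repeats)
  redrawn <- 0L
  set.seed(as.integer(seed))
  draw_seeds <- sample.int(2147483646L, n_repeats * 20L)
  draw_i <- 0L
  for (r in seq_len(n_repeats)) {
    repeat {
      draw_i <- draw_i + 1L
      if (draw_i > length(draw_seeds))
        stop("too many redraws: reference groups too small for holdout")
      set.seed(draw_seeds[draw_i])
      keep <- sort(sample.int(n, n - n_out))
      if (all(tabulate(reference$labels[keep], G) > 0)) break
      redrawn <- redrawn + 1L
      message("Redrew holdout ", r,
              ": a reference group vanished from the subsample")
    }
    sub <- cn_matrix(m$values[keep, , drop = FALSE], m$sample_ids[keep],
                     m$grid)
    sub_seed <- derive_seed(draw_seeds[draw_i], 17L, r)
    init <- ensure_nonempty(nmf_cluster(sub, G, seed = sub_seed,
                                        n_restarts = n_restarts))
    sc <- search_config(G = G, m_stop = cfg$m_stop, seed = sub_seed,
                        max_iters = cfg$max_iters)
    fit <- hmmc_search(sub, params, sc, init)
    err <- best_match_disagreements(reference$labels[keep],
                                    fit$assignment$labels, G)
    errors[r] <- err
    retained_n[r] <- length(keep)
  }
  list(error_rate = sum(errors) / sum(retained_n),
       per_repeat_errors = errors,
       per_repeat_retained = retained_n,
       redrawn = redrawn)
}

# Minimum number of label disagreements over all bijective relabelings of
# `pred` onto `ref` (both in 1..G).
best_match_disagreements <- function(ref, pred, G) {
  conf <- table(factor(pred, levels = 1:G), factor(ref, levels = 1:G))
  perms <- permutations(G)
  agree <- apply(perms, 1, function(p) sum(conf[cbind(1:G, p)]))
  length(ref) - max(agree)
}
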