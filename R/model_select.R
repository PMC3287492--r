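#' Bayesian Information Criterion for a G-group HMM clustering
#'
#' `BIC = -2 * logL + k * ln(n)` where the log-likelihood is the sum of the
#' per-group Viterbi delta values and the parameter count is `k = T * G`
#' (the decoded hidden state of each of the T segments in each of the G
#' groups; transition and emission parameters are estimated empirically
#' beforehand and not counted). Lower is better.
#'
#' @param total_loglik sum of per-group delta values.
#' @param T_segments number of segments T.
#' @param G number of groups.
#' @param n number of samples.
#' @return the BIC value.
#' @examples
#' bic_score(100, T_segments = 10, G = 2, n = exp(1))  # -200 + 20
#' @export
bic_score <- function(total_loglik, T_segments, G, n) {
  if (T_segments < 1 || G < 1 || n < 1) stop("T, G, n must be >= 1")
  -2 * total_loglik + T_segments * G * log(n)
}

#' Select the number of groups by BIC
#'
#' Runs the full clustering pipeline (NMF seed then label search) for each
#' candidate G, scores each result with [bic_score()], and returns the G
#' with the smallest BIC (ties broken toward the smaller, more
#' parsimonious G). `G = 1` is scored directly from the single-cluster
#' delta with no search.
#'
#' @param m a [cn_matrix()].
#' @param params an [hmm_params()]; if `NULL`, estimated from `m` via
#'   [fit_hmm_params()].
#' @param G_range integer vector of candidate group numbers (default 2:6).
#' @param cfg a [search_config()] whose seed spawns one sub-seed per G;
#'   its `G` field is ignored.
#' @param n_restarts NMF restarts for each seeding.
#' @return list with `best_G`, `scores` (data frame with columns `G`,
#'   `total_loglik`, `k`, `bic`), and `fits` (one `hmmc_fit` per G).
#' @export
select_G <- function(m, params = NULL, G_range = 2:6,
                     cfg = search_config(G = 2, seed = 1),
                     n_restarts = 10) {
  stopifnot(inherits(m, "cn_matrix"))
  if (length(G_range) == 0 || any(G_range < 1))
    stop("G_range must be non-empty with all values >= 1")
  if (is.null(params)) params <- fit_hmm_params(m)
  n <- nrow(m$values)
  T_n <- ncol(m$values)
  fits <- vector("list", length(G_range))
  scores <- data.frame(G = as.integer(G_range), total_loglik = NA_real_,
                       k = as.integer(G_range) * T_n, bic = NA_real_)
  for (i in seq_along(G_range)) {
    G <- G_range[i]
    sub_seed <- derive_seed(cfg$seed, 104729L, G)
    g_cfg <- search_config(G = G, m_stop = cfg$m_stop, seed = sub_seed,
                           max_iters = cfg$max_iters,
                           n_workers = cfg$n_workers)
    init <- if (G == 1) cluster_assignment(rep(1L, n), 1L)
            else ensure_nonempty(nmf_cluster(m, G, seed = sub_seed,
                                             n_restarts = n_restarts))
    fit <- hmmc_search(m, params, g_cfg, init)
    fits[[i]] <- fit
    scores$total_loglik[i] <- fit$total_loglik
    scores$bic[i] <- bic_score(fit$total_loglik, T_n, G, n)
  }
  best_G <- scores$G[which.min(scores$bic)]  # which.min ties to first;
  # G_range need not be sorted, so enforce smallest-G tie-break explicitly
  minimal <- scores$G[scores$bic <= min(scores$bic) + 0]
  best_G <- min(minimal)
  list(best_G = best_G, scores = scores, fits = fits)
}

# Deterministic sub-seed derivation, kept within 32-bit integer range.
derive_seed <- function(seed, mult, index) {
  as.integer((as.numeric(seed) * 31L + as.numeric(mult) * index) %%
               2147483647)
}

# Repair an assignment whose groups are not all occupied by moving one
# sample (deterministically, from the largest group) into each empty group.
ensure_nonempty <- function(a) {
  sizes <- group_sizes(a)
  labels <- a$labels
  for (g in which(sizes == 0)) {
    sizes <- tabulate(labels, a$G)
    donor_group <- which.max(sizes)
    donor <- which(labels == donor_group)[1]
    labels[donor] <- g
  }
  cluster_assignment(labels, a$G)
}
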