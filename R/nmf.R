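#' Cluster assignment container
#'
#' A partition of n samples into G groups, stored as a vector of integer
#' labels in 1..G.
#'
#' @param labels integer vector of group labels.
#' @param G number of groups; defaults to `max(labels)`.
#' @return object of class `cluster_assignment` with elements `labels`, `G`.
#' @export
cluster_assignment <- function(labels, G = max(labels)) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stop("empty label vector")
  if (G < 1) stop("G must be >= 1")
  if (any(labels < 1L) || any(labels > G))
    stop("labels must be in 1..G")
  structure(list(labels = labels, G = as.integer(G)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment:", length(x$labels), "samples in", x$G,
      "groups; sizes:", paste(tabulate(x$labels, x$G), collapse = ", "),
      "\n")
  invisible(x)
}

group_sizes <- function(a) tabulate(a$labels, a$G)

# Frobenius-loss NMF by multiplicative updates (Lee-Seung). Returns W, H
# and the final loss. Small dense problems only, which is all the seeding
# stage needs.
nmf_fit <- function(V, G, max_iter = 300, tol = 1e-6) {
  n <- nrow(V); T_n <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(n * G, 0.1, 1), n, G)
  H <- matrix(stats::runif(G * T_n, 0.1, 1), G, T_n)
  loss_prev <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V) / (crossprod(W, W %*% H) + eps))
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0) {
      loss <- sum((V - W %*% H)^2)
      if (is.finite(loss_prev) && loss_prev - loss < tol * loss_prev) break
      loss_prev <- loss
    }
  }
  list(W = W, H = H, loss = sum((V - W %*% H)^2))
}

#' Cluster samples by nonnegative matrix factorization
#'
#' Factorizes the nonnegative n x T copy-number matrix as W H with inner
#' rank G (Frobenius loss, multiplicative updates), keeping the best of
#' `n_restarts` random initializations, and assigns each sample to the
#' group whose coefficient in its row of W is largest (ties to the lowest
#' group index). This provides both the preliminary clustering that seeds
#' the HMM label search and the baseline method it is benchmarked against.
#'
#' @param m a [cn_matrix()] (all values are nonnegative by construction).
#' @param G number of groups, 1 <= G <= n. `G = 1` returns all-ones labels
#'   without factorizing.
#' @param seed integer seed for the random initializations.
#' @param n_restarts number of random restarts (default 10).
#' @return a [cluster_assignment()].
#' @examples
#' m <- generate_dataset(sim_config(s = 0.3, noise_amp_count = 0, seed = 1))
#' nmf_cluster(m$matrix, G = 2, seed = 1)
#' @export
nmf_cluster <- function(m, G, seed, n_restarts = 10) {
  stopifnot(inherits(m, "cn_matrix"))
  n <- nrow(m$values)
  if (G < 1) stop("G must be >= 1")
  if (G > n) stop("G must not exceed the number of samples")
  if (any(m$values < 0)) stop("matrix entries must be nonnegative")
  if (G == 1) return(cluster_assignment(rep(1L, n), 1L))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_fit(m$values, G)
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  labels <- max.col(best$W, ties.method = "first")
  cluster_assignment(labels, G)
}
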