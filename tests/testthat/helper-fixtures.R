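# Shared builders and independent oracles used across the test files.

# Tiny copy-number matrix on one chromosome.
toy_matrix <- function(vals, chrom = "1") {
  vals <- as.matrix(vals)
  g <- data.frame(chromosome = chrom,
                  start = seq_len(ncol(vals)) * 100L - 99L,
                  end = seq_len(ncol(vals)) * 100L)
  cn_matrix(vals, paste0("S", seq_len(nrow(vals))), g)
}

# Brute-force max-path oracle: enumerates all K^T state paths and returns
# the maximum joint log-probability. Independent of the Viterbi recursion.
brute_force_delta <- function(vals, params) {
  vals <- as.matrix(vals)
  T_n <- ncol(vals)
  K <- params$K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_n)))
  best <- -Inf
  for (i in seq_len(nrow(paths))) {
    path <- paths[i, ]
    lp <- log(params$initial[path[1]])
    if (T_n > 1)
      for (t in 2:T_n)
        lp <- lp + if (path[t] == path[t - 1]) log(params$p_same)
                   else log(params$p_diff)
    for (t in seq_len(T_n))
      lp <- lp + sum(emission_logdensity(vals[, t], params$states[path[t]],
                                         params$sigma))
    if (lp > best) best <- lp
  }
  best
}

# Exhaustive two-group partition oracle: best total log-likelihood over
# all bipartitions of n samples (labels fixed so sample 1 is in group 1).
exhaustive_bipartition_optimum <- function(m, params) {
  n <- nrow(m$values)
  stopifnot(n <= 12)
  ea <- hmmc:::emission_array(m, params)
  best <- -Inf
  best_lab <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    ll <- total_loglik(m, cluster_assignment(lab, 2), params, ea)$total
    if (ll > best) {
      best <- ll
      best_lab <- lab
    }
  }
  list(total = best, labels = best_lab)
}

# Strongly separated two-group dataset: many amplified segments so the
# subtype signal dominates both the search landscape and the BIC penalty,
# and independent noise so the emission model is well specified and the
# likelihood optimum provably sits at the planted partition. Used where
# tests need unambiguous recoverable structure; the autocorrelated-noise
# regime is exercised separately by the study-condition experiment.
separated_dataset <- function(seed, n_per_group = 6, T_segments = 60,
                              amp_segments = 15) {
  generate_dataset(sim_config(n_per_group = n_per_group,
                              T_segments = T_segments,
                              amp_segments = amp_segments,
                              s = 0.5, noise_amp_count = 0, rho = 0,
                              seed = seed))
}
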