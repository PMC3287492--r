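#' Simulation configuration for two-group aCGH benchmark data
#'
#' Describes a synthetic cohort of two equal groups of segment-level
#' copy-number profiles: both groups fluctuate around a diploid baseline
#' with AR(1)-correlated noise (mimicking the spatial correlation of
#' neighbouring SNPs on high-density arrays); the second group carries a
#' block of consecutive amplified segments in the middle of the genome
#' (the subtype signal); and every sample additionally receives a set of
#' randomly placed amplified segments (structured nuisance noise).
#'
#' @param n_per_group samples per group (default 10).
#' @param T_segments number of segments on one pseudo-chromosome
#'   (default 100).
#' @param baseline_mean diploid baseline copy number (default 2).
#' @param s marginal standard deviation of the AR(1) noise (default 1).
#' @param amp_segments number of consecutive amplified segments planted at
#'   the centre of the genome in group 2 (default 3).
#' @param amp_shift copy-number increase of the planted segments
#'   (default +2, i.e. mean 4).
#' @param noise_amp_count randomly amplified segments per sample
#'   (default 40).
#' @param noise_amp_shift copy-number increase of the random amplifications
#'   (default +2).
#' @param amp_mode how the random amplified segments are drawn:
#'   `"per_sample"` (default) draws an independent set for every sample;
#'   `"shared"` draws one set shared by the whole cohort; `"per_group"`
#'   draws one set per group, turning the random amplifications into
#'   group-level structure (the two sensitivity modes are discussed in the
#'   methods vignette). In every mode the draw is from the non-planted
#'   segments, so each sample carries exactly `noise_amp_count` (group 1)
#'   or `noise_amp_count + amp_segments` (group 2) amplified segments.
#' @param rho AR(1) lag-1 autocorrelation (default 0.9).
#' @param value_floor values are clamped below at this positive level,
#'   since emission densities require positive copy numbers (default 0.05).
#' @param seed integer seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 10, T_segments = 100,
                       baseline_mean = 2, s = 1, amp_segments = 3,
                       amp_shift = 2, noise_amp_count = 40,
                       noise_amp_shift = 2,
                       amp_mode = c("per_sample", "shared", "per_group"),
                       rho = 0.9, value_floor = 0.05, seed = 1) {
  amp_mode <- match.arg(amp_mode)
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (s <= 0) stop("s must be positive")
  if (amp_segments + noise_amp_count > T_segments)
    stop("planted plus noise segment counts must not exceed T")
  structure(list(n_per_group = as.integer(n_per_group),
                 T_segments = as.integer(T_segments),
                 baseline_mean = baseline_mean, s = s,
                 amp_segments = as.integer(amp_segments),
                 amp_shift = amp_shift,
                 noise_amp_count = as.integer(noise_amp_count),
                 noise_amp_shift = noise_amp_shift,
                 amp_mode = amp_mode,
                 rho = rho, value_floor = value_floor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Stationary AR(1) noise sequence
#'
#' Generates `e_t = rho * e_{t-1} + eps_t` with
#' `eps_t ~ N(0, s^2 (1 - rho^2))` and stationary initialization
#' `e_1 ~ N(0, s^2)`, so the marginal standard deviation is `s` at every
#' position and the lag-1 autocorrelation is `rho`. With `rho = 0` this is
#' i.i.d. `N(0, s^2)` noise.
#'
#' @param T_segments sequence length.
#' @param s marginal standard deviation.
#' @param rho lag-1 autocorrelation in \[0, 1).
#' @return numeric vector of length `T_segments`.
#' @export
ar1_noise <- function(T_segments, s, rho) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (s <= 0) stop("s must be positive")
  eps <- stats::rnorm(T_segments, 0, s * sqrt(1 - rho^2))
  e <- numeric(T_segments)
  e[1] <- stats::rnorm(1, 0, s)
  if (T_segments > 1)
    for (t in 2:T_segments) e[t] <- rho * e[t - 1] + eps[t]
  e
}

#' Generate a synthetic two-group copy-number dataset
#'
#' Each sample's profile is the group mean profile plus an independent
#' stationary AR(1) noise track, after which `noise_amp_count` non-planted
#' segment indices are drawn (per sample by default; see `amp_mode` in
#' [sim_config()]) and shifted up by `noise_amp_shift`; values are floored
#' at `cfg$value_floor` to stay positive. Group 2's mean profile carries
#' `amp_segments` consecutive segments centred at index `floor(T/2)`
#' raised by `amp_shift`. Rows 1..n_per_group are group 1.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset` with elements `matrix` (a
#'   [cn_matrix()] on one pseudo-chromosome), `truth` (the planted
#'   [cluster_assignment()] with G = 2), and `planted_segments` (indices
#'   of the group-2 amplified block).
#' @examples
#' d <- generate_dataset(sim_config(seed = 42))
#' dim(d$matrix$values)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- 2L * cfg$n_per_group
  T_n <- cfg$T_segments
  centre <- T_n %/% 2L
  half <- (cfg$amp_segments - 1L) %/% 2L
  planted <- if (cfg$amp_segments > 0)
    seq(centre - half, length.out = cfg$amp_segments) else integer(0)
  base_profile <- rep(cfg$baseline_mean, T_n)
  g2_profile <- base_profile
  g2_profile[planted] <- g2_profile[planted] + cfg$amp_shift
  vals <- matrix(NA_real_, n, T_n)
  pool <- setdiff(seq_len(T_n), planted)
  draw_amps <- function() sort(pool[sample.int(length(pool),
                                               cfg$noise_amp_count)])
  shared_idx <- group_idx <- NULL
  if (cfg$noise_amp_count > 0) {
    if (cfg$amp_mode == "shared") shared_idx <- draw_amps()
    if (cfg$amp_mode == "per_group")
      group_idx <- list(draw_amps(), draw_amps())
  }
  for (j in seq_len(n)) {
    in_g2 <- j > cfg$n_per_group
    mu <- if (in_g2) g2_profile else base_profile
    x <- mu + ar1_noise(T_n, cfg$s, cfg$rho)
    if (cfg$noise_amp_count > 0) {
      idx <- switch(cfg$amp_mode,
                    per_sample = draw_amps(),
                    shared = shared_idx,
                    per_group = group_idx[[if (in_g2) 2 else 1]])
      x[idx] <- x[idx] + cfg$noise_amp_shift
    }
    vals[j, ] <- pmax(x, cfg$value_floor)
  }
  grid <- data.frame(chromosome = "1",
                     start = seq_len(T_n) * 1000L - 999L,
                     end = seq_len(T_n) * 1000L)
  truth <- cluster_assignment(rep(1:2, each = cfg$n_per_group), 2L)
  structure(list(matrix = cn_matrix(vals, sprintf("S%02d", seq_len(n)),
                                    grid),
                 truth = truth, planted_segments = planted),
            class = "sim_dataset")
}

# All permutations of 1..k (k! rows); used for best-bijection matching.
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Best-relabelling clustering error rate
#'
#' The fraction of samples whose predicted group differs from the true
#' group, minimized over all bijective relabelings of the predicted
#' groups. This removes the arbitrary labelling of clusters: identical
#' partitions score 0 regardless of label names, and for G = 2 the error
#' can never exceed 0.5.
#'
#' @param truth a [cluster_assignment()] (or integer label vector).
#' @param predicted a [cluster_assignment()] (or integer label vector) of
#'   the same length.
#' @return error rate in \[0, 1\].
#' @examples
#' error_rate(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 0: same partition
#' error_rate(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 0.25
#' @export
error_rate <- function(truth, predicted) {
  tl <- if (inherits(truth, "cluster_assignment")) truth$labels
        else as.integer(truth)
  pl <- if (inherits(predicted, "cluster_assignment")) predicted$labels
        else as.integer(predicted)
  if (length(tl) != length(pl))
    stop("truth and predicted must have the same length")
  G <- max(tl, pl)
  if (G > 8) stop("relabelling enumeration supports G <= 8")
  conf <- table(factor(pl, levels = 1:G), factor(tl, levels = 1:G))
  perms <- permutations(G)
  agree <- apply(perms, 1, function(p) sum(conf[cbind(1:G, p)]))
  1 - max(agree) / length(tl)
}

#' Run the HMMC-vs-NMF misclassification experiment
#'
#' For each noise level `s` and each replicate, generates a two-group
#' dataset, clusters it once with NMF alone (rank 2, max-coefficient
#' assignment) and once with HMMC (G = 2, seeded by that same NMF
#' result), and records each method's best-relabelling error rate against
#' the planted truth. Replicate seeds are derived deterministically from
#' `base_cfg$seed`, the position of `s` in the grid, and the replicate
#' index.
#'
#' @param s_grid noise standard deviations to scan (default
#'   `c(0.5, 1, 1.5, 2)`).
#' @param n_datasets replicate datasets per `s` (default 200).
#' @param base_cfg a [sim_config()] template; its `s` and `seed` fields
#'   are overridden per replicate.
#' @param search_cfg a [search_config()] template for the HMMC runs; its
#'   seed is likewise derived per replicate.
#' @param n_restarts NMF restarts per dataset.
#' @return data frame with one row per (s, method) and columns `s`,
#'   `method` (`"HMMC"` or `"NMF"`), `mean_error_rate`, `n_datasets`; the
#'   per-replicate error matrix is attached as attribute `"replicates"`.
#' @export
run_error_experiment <- function(s_grid = c(0.5, 1, 1.5, 2),
                                 n_datasets = 200,
                                 base_cfg = sim_config(),
                                 search_cfg = search_config(G = 2),
                                 n_restarts = 5) {
  if (n_datasets < 1) stop("n_datasets must be >= 1")
  reps <- array(NA_real_, c(length(s_grid), n_datasets, 2),
                dimnames = list(s = s_grid, NULL,
                                method = c("HMMC", "NMF")))
  for (si in seq_along(s_grid)) {
    for (ri in seq_len(n_datasets)) {
      seed_d <- derive_seed(base_cfg$seed, 7919L, si * 100000L + ri)
      cfg <- base_cfg
      cfg$s <- s_grid[si]
      cfg$seed <- seed_d
      d <- generate_dataset(cfg)
      params <- fit_hmm_params(d$matrix)
      nmf_a <- ensure_nonempty(nmf_cluster(d$matrix, 2L, seed = seed_d,
                                           n_restarts = n_restarts))
      reps[si, ri, "NMF"] <- error_rate(d$truth, nmf_a)
      sc <- search_config(G = 2L, m_stop = search_cfg$m_stop,
                          seed = derive_seed(seed_d, 13L, 1L),
                          max_iters = search_cfg$max_iters)
      fit <- hmmc_search(d$matrix, params, sc, nmf_a)
      reps[si, ri, "HMMC"] <- error_rate(d$truth, fit$assignment)
    }
  }
  out <- expand.grid(s = s_grid, method = c("HMMC", "NMF"),
                     stringsAsFactors = FALSE)
  out$mean_error_rate <- mapply(function(s, meth)
    mean(reps[as.character(s), , meth]), out$s, out$method)
  out$n_datasets <- n_datasets
  out <- out[order(out$s, out$method), ]
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  out
}
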