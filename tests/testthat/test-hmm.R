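test_that("emission log-density matches the lognormal closed form", {
  # y at the state value: zero exponent term
  sigma <- 0.3
  expect_equal(emission_logdensity(2, 2, sigma),
               -log(2) - log(sigma) - 0.5 * log(2 * pi))
  # hand-evaluated: y = 4, state 2, sigma = ln 2 -> exponent term 1/2
  expect_equal(emission_logdensity(4, 2, log(2)),
               -log(4) - log(log(2)) - 0.5 * log(2 * pi) - 0.5)
  expect_error(emission_logdensity(-1, 2, 0.3), "positive")
})

test_that("emission density integrates to 1 over positive y", {
  for (st in c(0.1, 2, 5)) {
    q <- stats::integrate(function(y) exp(emission_logdensity(y, st, 0.4)),
                          0, Inf, rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
  }
})

test_that("sigma estimation averages per-segment log-scale sd", {
  # two samples whose log values differ by exactly 1 at every segment
  m <- toy_matrix(rbind(rep(2, 4), rep(2 * exp(1), 4)))
  expect_equal(estimate_emission_sd(m), 1 / sqrt(2))
  # scale invariance
  m10 <- toy_matrix(10 * m$values)
  expect_equal(estimate_emission_sd(m10), estimate_emission_sd(m))
  # degenerate zero spread floors at the minimum
  expect_equal(estimate_emission_sd(toy_matrix(matrix(2, 3, 4))), 0.05)
  expect_error(estimate_emission_sd(toy_matrix(matrix(2, 1, 4))),
               "sigma")
})

test_that("transition estimation counts same/different state pairs", {
  # constant diploid matrix: p_same near 1, kept below 1 by smoothing
  m <- toy_matrix(matrix(2, 3, 10))
  tr <- estimate_transition_probs(m)
  expect_gt(tr$p_same, 0.9)
  expect_lt(tr$p_same, 1)
  expect_gt(tr$p_diff, 0)
  expect_equal(tr$p_same + 5 * tr$p_diff, 1)

  # alternating 2,4 in every sample: all transitions differ
  alt <- toy_matrix(matrix(rep(c(2, 4), 5), 2, 10, byrow = TRUE))
  tr2 <- estimate_transition_probs(alt)
  # 2 samples x 9 adjacent pairs, none same; add-one smoothing
  expect_equal(tr2$p_same, (0 + 1) / (18 + 2))
  expect_equal(tr2$p_same + 5 * tr2$p_diff, 1)
})

test_that("discretization sends midpoint ties to the lower state", {
  states <- c(0.1, 1.5, 2, 3, 4, 5)
  d <- hmmc:::discretize_to_states(matrix(c(2.5, 2.5 + 1e-9, 2.49, 1.75)),
                                   states)
  expect_equal(as.integer(d), c(3L, 4L, 3L, 2L))
})

test_that("single-segment Viterbi reduces to initial + best emission", {
  m <- toy_matrix(matrix(2, 1, 1))
  p <- hmm_params(sigma = 0.3)
  fit <- cluster_delta(m, 1, p)
  expect_equal(fit$delta,
               log(1 / 6) - log(2) - log(0.3) - 0.5 * log(2 * pi))
  expect_equal(fit$path, 3L)  # state value 2
})

test_that("cluster_delta equals brute-force path enumeration", {
  set.seed(11)
  for (rep in 1:25) {
    T_n <- sample(1:4, 1)
    ns <- sample(1:3, 1)
    vals <- matrix(exp(rnorm(ns * T_n, log(2), 0.6)), ns, T_n)
    p <- hmm_params(p_same = runif(1, 0.05, 0.95),
                    sigma = runif(1, 0.1, 1))
    fit <- cluster_delta(toy_matrix(vals), seq_len(ns), p)
    expect_equal(fit$delta, brute_force_delta(vals, p), tolerance = 1e-9)
  }
})

test_that("chromosome boundaries restart the chain", {
  p <- hmm_params(sigma = 0.3)
  vals <- matrix(c(2, 2, 4, 4), 1, 4)
  # one chromosome: one transition 2->4 paid at the boundary
  one <- cluster_delta(toy_matrix(vals), 1, p)
  # two chromosomes of 2 segments: no cross-chromosome transition,
  # but a second initial-distribution term
  g2 <- data.frame(chromosome = c("1", "1", "2", "2"),
                   start = c(1L, 101L, 1L, 101L),
                   end = c(100L, 200L, 100L, 200L))
  two <- cluster_delta(cn_matrix(vals, "S1", g2), 1, p)
  # the 2->4 jump cost is replaced by a fresh initial term
  expect_equal(two$delta - one$delta, log(1 / 6) - log(p$p_diff))
  expect_equal(two$path, c(3L, 3L, 5L, 5L))
})

test_that("delta decomposes: duplicating members doubles emissions only", {
  set.seed(3)
  vals <- matrix(exp(rnorm(8, log(2), 0.4)), 2, 4)
  m1 <- toy_matrix(vals)
  m2 <- toy_matrix(rbind(vals, vals))
  p <- hmm_params(sigma = 0.4)
  d1 <- cluster_delta(m1, 1:2, p)
  d2 <- cluster_delta(m2, 1:4, p)
  # transition+initial part of the (identical) best path
  path_lp <- log(1 / 6) +
    sum(ifelse(diff(d1$path) == 0, log(p$p_same), log(p$p_diff)))
  expect_equal(d2$path, d1$path)
  expect_equal(d2$delta - path_lp, 2 * (d1$delta - path_lp))
})

test_that("cluster_delta is invariant to member order and small sigma
           recovers planted states", {
  set.seed(9)
  vals <- matrix(exp(rnorm(12, log(2), 0.3)), 3, 4)
  m <- toy_matrix(vals)
  p <- hmm_params(sigma = 0.3)
  expect_equal(cluster_delta(m, c(3, 1, 2), p)$delta,
               cluster_delta(m, 1:3, p)$delta)

  # data exactly at state values, tiny sigma: path recovers them
  planted <- c(2, 2, 4, 4, 3, 0.1)
  mp <- toy_matrix(matrix(rep(planted, 2), 2, 6, byrow = TRUE))
  fit <- cluster_delta(mp, 1:2, hmm_params(sigma = 0.05))
  expect_equal(hmm_params()$states[fit$path], planted)
})

test_that("hmm_params validates its invariants", {
  p <- hmm_params(p_same = 0.56)
  expect_equal(p$p_same + (p$K - 1) * p$p_diff, 1, tolerance = 1e-12)
  expect_equal(sum(p$initial), 1)
  expect_error(hmm_params(p_same = 1.2), "p_same")
  expect_error(hmm_params(sigma = -1), "sigma")
  expect_error(hmm_params(states = c(2, 1)), "increasing")
})
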