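# Emissions, votes, kernels, transitions, consensus and the
# constrained-Viterbi weight update.

OBS <- c("mistake", "explore", "hit")

test_that("emissions follow the path-set ratios with the mistake fallback", {
  iface <- test_interface()
  st <- reset_for_task(strategy_state("spatial", iface), "0000", iface)
  e <- emission_probs(st, candidate_paths(st, "", "0000"))
  expect_equal(unname(e), c(0, 15 / 16, 1 / 16))
  expect_equal(sum(e), 1)
  # rules violated: both sets empty
  e0 <- emission_probs(st, list(H = character(0), H_star = character(0)))
  expect_equal(unname(e0), c(1, 0, 0))
  # random always emits (1, 0, 0)
  rnd <- strategy_state("random", iface)
  expect_equal(unname(emission_probs(rnd, candidate_paths(rnd, "", "0000"))),
               c(1, 0, 0))
})

test_that("votes self-link best explainers and split the rest", {
  # one strategy uniquely best for explore; the other donates its mass
  E <- rbind(a = c(0.1, 0.9, 0.0), b = c(0.2, 0.6, 0.2))
  l <- step_votes(E)
  expect_equal(l["b", "a"], 0.6)            # case (b): donated in full
  expect_equal(l["a", "a"], 0.9)            # self-link for explore only
  expect_equal(l["a", "b"], 0.1)            # mistake mass goes to b
  expect_equal(l["b", "b"], 0.4)            # mistake + hit self-links
  expect_equal(unname(rowSums(l)), c(1, 1))

  # all four emit (1,0,0): everyone self-links; U = {random} only
  E4 <- matrix(rep(c(1, 0, 0), each = 4L), 4L, 3L)
  l4 <- step_votes(E4, random_index = 1L)
  expect_equal(unname(diag(l4)), rep(1, 4))
  expect_equal(l4[1L, 1L], 1)

  # three strategies with P(mistake)=0: |U| = 4, each random-row link 0.25
  E3 <- rbind(c(1, 0, 0), c(0, 0.9, 0.1), c(0, 0.8, 0.2), c(0, 0.5, 0.5))
  l3 <- step_votes(E3, random_index = 1L)
  expect_equal(unname(l3[1L, ]), rep(0.25, 4L))
  expect_equal(unname(rowSums(l3)), rep(1, 4L))
})

test_that("the observation kernel peaks at the current step", {
  expect_equal(kernel_weight(10, 10, 20), 1)
  expect_equal(kernel_weight(10 - 20, 10, 20), exp(-1 / 2))
  expect_equal(kernel_weight(10 - 60, 10, 20), exp(-4.5))
  expect_error(kernel_weight(1, 2, 0), "positive")
})

test_that("transition matrices kernel-average the vote history", {
  l1 <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  hist1 <- array(l1, dim = c(1L, 2L, 2L))
  expect_equal(transition_matrix(hist1, 1L, 20), l1)
  # constant votes equal the constant for any sigma
  hist5 <- array(rep(l1, each = 5L), dim = c(5L, 2L, 2L))
  for (s in c(1, 20)) {
    expect_equal(transition_matrix(hist5, 5L, s), l1)
  }
  # small kernels track the most recent vote more closely
  l2 <- rbind(c(0.9, 0.1), c(0.6, 0.4))
  hist2 <- array(c(l1, l2), dim = c(2L, 2L, 2L))
  hist2[1L, , ] <- l1; hist2[2L, , ] <- l2
  d_narrow <- max(abs(transition_matrix(hist2, 2L, 1) - l2))
  d_wide <- max(abs(transition_matrix(hist2, 2L, 20) - l2))
  expect_lt(d_narrow, d_wide)
  # empty history: identity prior
  expect_equal(transition_matrix(NULL, 0L, 20, n_strategies = 3L), diag(3L))
  # rows stay stochastic
  expect_equal(unname(rowSums(transition_matrix(hist2, 2L, 5))), c(1, 1))
})

test_that("consensus takes the largest summed emission with explore-first ties", {
  E <- matrix(rep(c(1, 0, 0), each = 4L), 4L, 3L)
  expect_equal(consensus_observation(E), "mistake")
  # three near-explore strategies outvote the random mistake
  E2 <- rbind(c(1, 0, 0), c(0, 0.9375, 0.0625), c(0, 0.9375, 0.0625),
              c(0, 0.9375, 0.0625))
  expect_equal(consensus_observation(E2), "explore")
  E3 <- rbind(c(1, 0, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))
  expect_equal(consensus_observation(E3), "hit")
  # exact tie: explore beats hit beats mistake
  Etie <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(consensus_observation(Etie), "explore")
})

test_that("a single-strategy system keeps weight 1", {
  E <- matrix(c(0, 0.6, 0.4), 1L, 3L)
  res <- update_weights(1, E, matrix(1, 1L, 1L), c("explore", "explore"),
                        2L, 20)
  expect_equal(res$w, 1)
})

test_that("a zero-weight strategy re-enters through its self-transition prior", {
  E <- rbind(c(0, 0.5, 0.5), c(0, 0.5, 0.5))
  L <- rbind(c(0.7, 0.3), c(0.3, 0.7))
  res <- update_weights(c(1, 0), E, L, c("explore", "hit"), 2L, 5)
  expect_gt(res$w[2L], 0)
})

test_that("weight updates match the exhaustive Viterbi oracle", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:3, 1L)
    E <- random_emissions(n)
    L <- random_stochastic(n)
    w <- stats::runif(n)
    w <- w / sum(w)
    if (rep %% 3L == 0L) w[sample(n, 1L)] <- 0
    t <- sample(2:6, 1L)
    obs <- sample(OBS, t, replace = TRUE)
    sigma <- stats::runif(1, 0.5, 25)
    got <- update_weights(w, E, L, obs, t, sigma)$raw
    want <- oracle_raw_weights(w, E, L, obs, t, sigma)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("inactive strategies earn nothing and rejoin later", {
  E <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 0.8, 0.2))
  L <- diag(3L)
  res <- update_weights(c(0.3, 0.3, 0.4), E, L,
                        c("mistake", "mistake"), 2L, 10,
                        active = c(TRUE, FALSE, TRUE))
  expect_equal(res$raw[2L], 0)
  expect_gt(res$raw[1L], 0)
  # matches the oracle under the same activity flags
  set.seed(11)
  for (rep in 1:20) {
    n <- 3L
    E <- random_emissions(n)
    act <- c(TRUE, sample(c(TRUE, FALSE), 2L, replace = TRUE))
    E[!act, ] <- rep(c(1, 0, 0), each = sum(!act))
    L <- random_stochastic(n)
    w <- rep(1 / 3, 3L)
    obs <- sample(OBS, 4L, replace = TRUE)
    want <- oracle_raw_weights(w, E, L, obs, 4L, 8, active = act)
    if (all(want == 0)) {
      # no active strategy explains any observed evidence
      expect_error(update_weights(w, E, L, obs, 4L, 8, active = act),
                   "cannot normalize")
    } else {
      got <- update_weights(w, E, L, obs, 4L, 8, active = act)$raw
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("identical domains report only the most knowledgeable strategy", {
  E <- rbind(c(1, 0, 0), c(0, 0.9, 0.1), c(0, 0.9, 0.1))
  L <- diag(3L)
  res <- update_weights(rep(1 / 3, 3L), E, L, "explore", 1L, 10,
                        domains = list(NULL, c("a", "b"), c("b", "a")),
                        alphas = c(1, 0.8, 0.4))
  expect_equal(res$participating, c(1L, 3L))
  expect_equal(res$w[2L], 0)
  expect_equal(sum(res$w), 1)
  # the excluded strategy's mass is still carried in w_all
  expect_gt(res$w_all[2L], 0)
})

test_that("the mixed knowledge gap is a convex combination", {
  expect_equal(mixed_alpha(c(1, 0.5, 0.25, 0), c(0.1, 0.2, 0.3, 0.4)), 0.275)
  expect_equal(mixed_alpha(rep(1, 4L), rep(0.25, 4L)), 1)
  expect_equal(mixed_alpha(c(0, 1), c(1, 0)), 0)
  set.seed(3)
  for (rep in 1:20) {
    a <- stats::runif(4L)
    w <- stats::rexp(4L); w <- w / sum(w)
    expect_gte(mixed_alpha(a, w), min(a) - 1e-12)
    expect_lte(mixed_alpha(a, w), max(a) + 1e-12)
  }
})

test_that("wide kernels approach the unweighted vote mean", {
  set.seed(5)
  hist <- array(stats::runif(10 * 2 * 2), dim = c(10L, 2L, 2L))
  for (s in seq_len(10L)) hist[s, , ] <- hist[s, , ] / rowSums(hist[s, , ])
  L_inf <- transition_matrix(hist, 10L, 1e6)
  L_mean <- apply(hist, c(2L, 3L), mean)
  expect_equal(L_inf, L_mean, tolerance = 1e-6)
})
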