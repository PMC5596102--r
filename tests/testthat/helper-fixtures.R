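# Shared fixtures and independent oracles. Everything is generated in code;
# expensive simulations/traces are cached for the duration of the test run.

.fix <- new.env(parent = emptyenv())

test_interface <- function(seed = 1L, depth = 4L) {
  key <- paste0("iface_", depth, "_", seed)
  if (is.null(.fix[[key]])) .fix[[key]] <- build_interface(depth, seed = seed)
  .fix[[key]]
}

# canonical simulated session, cached by (kind, agent seed, order seed)
fixture_log <- function(kind, agent_seed = 1L, order_seed = 1L, ...) {
  key <- paste("log", kind, agent_seed, order_seed, sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- simulate_session(
      agent_policy(kind, rng_seed = agent_seed, ...),
      test_interface(),
      session_config(rng_seed = order_seed)
    )
  }
  .fix[[key]]
}

fixture_trace <- function(kind, agent_seed = 1L, order_seed = 1L,
                          keep_internals = FALSE) {
  key <- paste("trace", kind, agent_seed, order_seed, keep_internals,
               sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- track_session(fixture_log(kind, agent_seed, order_seed),
                                 keep_internals = keep_internals)
  }
  .fix[[key]]
}

# The six canonical fixture agents (pure kinds, one mixture, one noisy).
canonical_logs <- function() {
  if (is.null(.fix$canonical)) {
    iface <- test_interface()
    cfg <- session_config(rng_seed = 1L)
    pols <- list(
      agent_policy("random", rng_seed = 1L),
      agent_policy("spatial", rng_seed = 1L),
      agent_policy("generative", rng_seed = 1L),
      agent_policy("discriminative", rng_seed = 1L),
      agent_policy("mixture", base_kind = "spatial",
                   schedule = data.frame(task_index = 5L,
                                         kind = "discriminative"),
                   rng_seed = 1L),
      agent_policy("noisy", base_kind = "discriminative", rng_seed = 1L)
    )
    .fix$canonical <- lapply(pols, simulate_session, interface = iface,
                             config = cfg)
    names(.fix$canonical) <- vapply(pols, `[[`, character(1), "kind")
  }
  .fix$canonical
}

canonical_traces <- function() {
  if (is.null(.fix$canonical_traces)) {
    .fix$canonical_traces <- lapply(canonical_logs(), track_session,
                                    keep_internals = TRUE)
  }
  .fix$canonical_traces
}

# fully knowledgeable observer states (exploitation limit)
full_knowledge_states <- function(iface = test_interface()) {
  stats::setNames(
    lapply(c("random", "spatial", "generative", "discriminative"),
           strategy_state, interface = iface, full_knowledge = TRUE),
    c("random", "spatial", "generative", "discriminative")
  )
}

# A session by an agent that already knows everything: clicks the target
# path from the first trial of every task.
oracle_agent_log <- function(agent_seed = 5L, order_seed = 6L) {
  key <- paste("oracle", agent_seed, order_seed, sep = "_")
  if (is.null(.fix[[key]])) {
    ag <- make_agent(agent_policy("discriminative", rng_seed = agent_seed),
                     test_interface(), full_knowledge = TRUE)
    .fix[[key]] <- simulate_session(ag,
                                    config = session_config(rng_seed = order_seed))
  }
  .fix[[key]]
}

# ---- independent oracles ---------------------------------------------------

# Brute-force candidate-path sets by direct enumeration of all bit vectors.
oracle_candidate_sets <- function(D, target, trial_prefix, depth) {
  combos <- expand.grid(rep(list(c("0", "1")), depth), stringsAsFactors = FALSE)
  paths <- apply(combos, 1L, paste0, collapse = "")
  H <- character(0); H_star <- character(0)
  for (p in paths) {
    if (!startsWith(p, trial_prefix)) next
    locs <- vapply(seq_len(depth), function(l) substr(p, 1L, l), character(1))
    tlocs <- vapply(seq_len(depth), function(l) substr(target, 1L, l), character(1))
    if (all(locs %in% tlocs)) H_star <- c(H_star, p)
    else if (all(locs %in% D)) H <- c(H, p)
  }
  list(H = sort(H), H_star = H_star)
}

# Exhaustive constrained-Viterbi weight enumeration: recursive search over
# node sequences with distinct interior nodes and an unrestricted final
# node, final edge in the best-link set. Written independently of the
# package's vectorized incidence-matrix implementation.
oracle_raw_weights <- function(w, E, L, obs_history, t, sigma,
                               active = NULL) {
  n <- nrow(E)
  if (is.null(active)) active <- rep(TRUE, n)
  obs_levels <- c("mistake", "explore", "hit")
  tau_v <- sapply(obs_levels, function(v) {
    idx <- which(obs_history == v)
    if (!length(idx)) 0 else sum(exp(-((idx - t)^2) / (2 * sigma^2)))
  })
  prior <- ifelse(w > 0, w, diag(L))
  raw <- numeric(n)
  for (vi in seq_len(3L)) {
    if (tau_v[vi] == 0) next
    Ev <- E[, vi]
    Ev[!active] <- 0
    if (all(Ev == 0)) next
    lv <- L * matrix(Ev, n, n, byrow = TRUE)
    mx <- max(lv)
    is_best <- lv >= mx - 1e-12 * max(1, abs(mx))
    for (i in seq_len(n)) {
      best_cost <- 0
      rec <- function(nodes, cost) {
        last <- nodes[length(nodes)]
        for (j in seq_len(n)) {
          extended <- cost * L[last, j] * Ev[j]
          if (is_best[last, j]) best_cost <<- max(best_cost, extended)
          if (!(j %in% nodes)) rec(c(nodes, j), extended)
        }
      }
      rec(i, prior[i] * Ev[i])
      raw[i] <- raw[i] + best_cost * tau_v[vi]
    }
  }
  raw
}

# random emission matrix (rows sum to 1)
random_emissions <- function(n) {
  E <- matrix(stats::rexp(n * 3L), n, 3L)
  E / rowSums(E)
}

# random right-stochastic matrix
random_stochastic <- function(n) {
  L <- matrix(stats::rexp(n * n), n, n)
  L / rowSums(L)
}
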