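#' Behavioral model primitives
#'
#' The observer interprets every click through the observation alphabet
#' `V = {mistake, explore, hit}`. Each strategy emits a distribution over
#' `V` computed from its candidate path sets; per-step votes between
#' strategies, accumulated under a Gaussian observation window, yield
#' time-varying transition probabilities; strategy weights are updated by a
#' Viterbi-style optimization constrained to each observation.
#'
#' @name behavioral-model
NULL

LOGZERO <- -1e9   # stands in for log(0); exp() underflows to exactly 0

log0 <- function(x) {
  out <- rep(LOGZERO, length(x))
  pos <- x > 0
  out[pos] <- log(x[pos])
  out
}

argmax_set <- function(x, tol = 1e-12) {
  mx <- max(x)
  which(x >= mx - tol * max(1, abs(mx)))
}

#' Emission probabilities of a strategy
#'
#' Over `V = (mistake, explore, hit)`: if the strategy's rules leave any
#' candidate path open, the emission is
#' `(0, |H|/(|H|+|H*|), |H*|/(|H|+|H*|))`; when the rules cannot explain
#' the current actions (both sets empty) the emission is fixed to
#' `(1, 0, 0)`. The random strategy always emits `(1, 0, 0)`.
#'
#' @param state A [strategy_state()].
#' @param sets Candidate path sets from [candidate_paths()].
#' @return Named numeric vector of length 3 summing to 1.
#' @export
emission_probs <- function(state, sets) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$kind == "random") {
    return(c(mistake = 1, explore = 0, hit = 0))
  }
  nh <- length(sets$H)
  ns <- length(sets$H_star)
  if (nh > 0L || ns > 0L) {
    c(mistake = 0, explore = nh / (nh + ns), hit = ns / (nh + ns))
  } else {
    c(mistake = 1, explore = 0, hit = 0)
  }
}

#' Per-step transition votes between strategies
#'
#' For each observation `v`, the strategies that best explain `v` (the
#' argmax of `P(v|s_i)`) strengthen their self-links by `P(v|s_i)`, while
#' every other strategy splits its own `P(v|s_i)` equally among the best
#' explainers. The random strategy's fixed `(1,0,0)` emissions would
#' otherwise never link it to learning strategies, so its row is overridden:
#' it votes `1/|U|` for every strategy in
#' `U = {s_i : P(mistake|s_i) = 0} ∪ {random}`. Every row sums to 1.
#'
#' @param emissions A matrix with one row per strategy and the three
#'   observation columns (mistake, explore, hit).
#' @param random_index Row index of the random strategy, or `NULL` if the
#'   system has none (toy systems).
#' @param active Optional logical vector: strategies whose rules are
#'   violated at this step (the `(1,0,0)` fallback) are *inactive*. An
#'   inactive strategy still distributes its votes, but is not a candidate
#'   best explainer — a mistake is evidence for the random strategy, not
#'   for the strategy whose rules were broken. `NULL` (default) treats all
#'   strategies as active, which reduces to the plain argmax scheme.
#' @return The vote matrix `l` (rows = from, columns = to).
#' @export
step_votes <- function(emissions, random_index = NULL, active = NULL) {
  E <- as.matrix(emissions)
  n <- nrow(E)
  if (is.null(active)) active <- rep(TRUE, n)
  if (!is.null(random_index)) active[random_index] <- TRUE
  l <- matrix(0, n, n, dimnames = list(rownames(E), rownames(E)))
  cand <- which(active)
  for (v in seq_len(ncol(E))) {
    B <- cand[argmax_set(E[cand, v])]
    for (i in seq_len(n)) {
      if (i %in% B) {
        l[i, i] <- l[i, i] + E[i, v]
      } else {
        l[i, B] <- l[i, B] + E[i, v] / length(B)
      }
    }
  }
  if (!is.null(random_index)) {
    U <- union(which(E[, 1L] == 0), random_index)
    l[random_index, ] <- 0
    l[random_index, U] <- 1 / length(U)
  }
  l
}

#' Gaussian observation-window weight
#'
#' `tau(n) = exp(-(n - t)^2 / (2 sigma^2))`, maximal (= 1) at the current
#' step `n = t`.
#'
#' @param n Past step index (or vector of them).
#' @param t Current step.
#' @param sigma Kernel width in steps.
#' @return Kernel weight(s) in `(0, 1]`.
#' @export
kernel_weight <- function(n, t, sigma) {
  if (sigma <= 0) stopf("`sigma` must be positive")
  exp(-((n - t)^2) / (2 * sigma^2))
}

#' Kernel-weighted transition probabilities
#'
#' The cumulative transition matrix `L` is the Gaussian-kernel weighted
#' average of the per-step vote matrices over steps `1..t`; each row is a
#' probability distribution. With no history yet, `L` is the identity
#' (every strategy self-transitions).
#'
#' @param vote_history A `steps x n x n` array of per-step vote matrices
#'   (or `NULL`/zero steps for the empty history).
#' @param t Current step (votes at array slice `s` are for step `s`).
#' @param sigma Kernel width in steps.
#' @param n_strategies Number of strategies (needed for the empty-history
#'   identity prior).
#' @return The `n x n` transition matrix.
#' @export
transition_matrix <- function(vote_history, t, sigma, n_strategies = NULL) {
  if (is.null(vote_history) || (is.array(vote_history) && dim(vote_history)[1L] == 0L)) {
    if (is.null(n_strategies)) stopf("`n_strategies` needed for empty history")
    return(diag(n_strategies))
  }
  d <- dim(vote_history)
  steps <- seq_len(d[1L])
  tau <- kernel_weight(steps, t, sigma)
  flat <- matrix(vote_history, nrow = d[1L])   # steps x (n*n)
  L <- colSums(flat * tau) / sum(tau)
  matrix(L, d[2L], d[3L], dimnames = dimnames(vote_history)[-1L])
}

#' Consensus observation
#'
#' The observation with the greatest summed emission probability across
#' strategies; ties are broken by the fixed precedence
#' explore > hit > mistake (the weakest claim about the participant).
#'
#' @param emissions Matrix with one row per strategy, columns
#'   (mistake, explore, hit).
#' @return One of `"mistake"`, `"explore"`, `"hit"`.
#' @export
consensus_observation <- function(emissions) {
  E <- as.matrix(emissions)
  totals <- colSums(E)
  names(totals) <- OBSERVATIONS
  prec <- c("explore", "hit", "mistake")
  winners <- OBSERVATIONS[argmax_set(totals)]
  prec[prec %in% winners][1L]
}

# ---- constrained-Viterbi path machinery ------------------------------------

# Enumerate the constrained-Viterbi candidate paths for an n-strategy
# system once: node sequences x0..x_{m-1} with no repeats, followed by an
# unrestricted final node (an optimal chain can always be shortened so
# that only its final node revisits an earlier one — interior loops only
# multiply in factors <= 1, but the final edge is pinned to the best-link
# set and may legitimately return, e.g. i -> j -> i). Returns incidence
# matrices for vectorized cost evaluation.
viterbi_paths <- function(n) {
  cache <- .viterbi_cache
  key <- as.character(n)
  if (!is.null(cache[[key]])) return(cache[[key]])
  seqs <- list()
  grow <- function(seq) {
    seqs[[length(seqs) + 1L]] <<- seq
    for (j in setdiff(seq_len(n), seq)) grow(c(seq, j))
  }
  for (i in seq_len(n)) grow(i)
  paths <- list()
  for (s in seqs) {
    for (j in seq_len(n)) {
      paths[[length(paths) + 1L]] <- c(s, j)
    }
  }
  P <- length(paths)
  A_edge <- matrix(0, P, n * n)     # counts of directed edges (from,to)
  A_node <- matrix(0, P, n)         # counts of emitting nodes
  start <- integer(P)
  final_edge <- integer(P)
  for (p in seq_len(P)) {
    x <- paths[[p]]
    start[p] <- x[1L]
    A_node[p, x[1L]] <- A_node[p, x[1L]] + 1
    for (r in 2L:length(x)) {
      e <- (x[r] - 1L) * n + x[r - 1L]   # column-major index into L
      A_edge[p, e] <- A_edge[p, e] + 1
      A_node[p, x[r]] <- A_node[p, x[r]] + 1
    }
    x_m <- x[length(x)]
    x_k <- x[length(x) - 1L]
    final_edge[p] <- (x_m - 1L) * n + x_k
  }
  out <- list(A_edge = A_edge, A_node = A_node, start = start,
              final_edge = final_edge,
              by_start = split(seq_len(P), start))
  cache[[key]] <- out
  out
}

.viterbi_cache <- new.env(parent = emptyenv())

#' Update strategy weights by observation-constrained Viterbi costs
#'
#' For each observation `v`, the best transition links are the argmax of
#' `P(s_k -> s_j) P(v|s_j)`; each strategy's cost is the maximum, over
#' simple strategy paths starting at it and ending in a best link, of the
#' product `prior_i P(v|s_i) * prod(P(s_a -> s_b) P(v|s_b))`. The prior for
#' strategy `i` is its current weight when positive and its self-transition
#' `L_ii` otherwise (so strategies with zero weight can re-enter). The
#' per-observation costs are weighted by the kernel relevance
#' `tau_v(t) = sum_n tau(n) [v(n) = v]` of that observation in the history
#' and summed, then normalized.
#'
#' When two strategies currently have identical domains of action, only the
#' one with the smallest knowledge gap takes part in the normalization (the
#' reported distribution); the other's weight is carried forward so it can
#' rejoin when the domains diverge. This rule applies to the systematic
#' strategies only — the random strategy's emissions are fixed rather than
#' domain-derived.
#'
#' @param w Current normalized weight vector (length n).
#' @param emissions `n x 3` emission matrix for the current step.
#' @param L Current `n x n` transition matrix.
#' @param observation_history Character vector of consensus observations
#'   for steps `1..t` (the current step included).
#' @param t Current step.
#' @param sigma Kernel width in steps.
#' @param domains Optional list of domain-of-action sets used for the
#'   identical-domain rule (`NULL` entries are ignored).
#' @param alphas Optional numeric vector of knowledge gaps (required when
#'   `domains` is given).
#' @param active Optional logical vector marking strategies whose rules
#'   are violated at this step as inactive: they are skipped as best-link
#'   targets and earn no cost at this step (their weight re-enters later
#'   through the `L_ii` prior). `NULL` treats everyone as active.
#' @return A list with `raw` (unnormalized costs), `w_all` (normalized over
#'   all strategies, the next step's prior), `w` (normalized over the
#'   participating set; zeros elsewhere) and `participating` (indices).
#' @export
update_weights <- function(w, emissions, L, observation_history, t, sigma,
                           domains = NULL, alphas = NULL, active = NULL) {
  E <- as.matrix(emissions)
  n <- nrow(E)
  stopifnot(length(w) == n, nrow(L) == n, ncol(L) == n)
  if (is.null(active)) active <- rep(TRUE, n)
  tau_v <- vapply(OBSERVATIONS, function(v) {
    idx <- which(observation_history == v)
    if (!length(idx)) 0 else sum(kernel_weight(idx, t, sigma))
  }, numeric(1))

  prior <- ifelse(w > 0, w, diag(L))
  vp <- viterbi_paths(n)
  logL <- log0(as.numeric(L))
  raw <- numeric(n)
  for (v in seq_len(3L)) {
    if (tau_v[v] == 0) next
    Ev <- E[, v]
    Ev[!active] <- 0       # inactive strategies cannot explain this step
    if (all(Ev == 0)) next
    link_val <- L * rep(Ev, each = n)      # L[k, j] * E[j]
    best <- argmax_set(as.numeric(link_val))
    valid <- vp$final_edge %in% best
    logc <- as.numeric(vp$A_edge %*% logL) +
      as.numeric(vp$A_node %*% log0(Ev)) +
      log0(prior)[vp$start]
    for (i in seq_len(n)) {
      idx <- vp$by_start[[i]]
      idx <- idx[valid[idx]]
      if (length(idx)) {
        raw[i] <- raw[i] + exp(max(logc[idx])) * tau_v[v]
      }
    }
  }

  participating <- seq_len(n)
  if (!is.null(domains)) {
    if (is.null(alphas)) stopf("`alphas` required with `domains`")
    keyed <- which(!vapply(domains, is.null, logical(1)))
    if (length(keyed) > 1L) {
      keys <- vapply(keyed, function(i) paste(sort(domains[[i]]), collapse = ","),
                     character(1))
      drop <- integer(0)
      for (k in unique(keys)) {
        grp <- keyed[keys == k]
        if (length(grp) > 1L) {
          keep <- grp[order(alphas[grp], grp)][1L]
          drop <- c(drop, setdiff(grp, keep))
        }
      }
      participating <- setdiff(participating, drop)
    }
  }

  W_all <- sum(raw)
  if (W_all <= 0) stopf("all strategy weights are zero; cannot normalize")
  W <- sum(raw[participating])
  if (W <= 0) {
    # the duplicate-domain representatives carry no mass at this step;
    # renormalize over the strategies that do
    participating <- which(raw > 0)
    W <- sum(raw[participating])
  }
  w_part <- numeric(n)
  w_part[participating] <- raw[participating] / W
  list(raw = raw, w_all = raw / W_all, w = w_part,
       participating = participating)
}

#' Mixed knowledge gap (behavioral learning curve)
#'
#' The behavioral model's knowledge gap is the weight-mixed gap
#' `alpha* = sum_i alpha_i w_i`; the participant's approximate learning
#' curve is `1 - alpha*`.
#'
#' @param alphas Numeric vector of per-strategy knowledge gaps.
#' @param w Normalized weight vector.
#' @return `alpha*` in `[0, 1]`.
#' @export
mixed_alpha <- function(alphas, w) {
  stopifnot(length(alphas) == length(w))
  sum(alphas * w)
}
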