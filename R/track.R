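#' Track a session with the behavioral model
#'
#' Replays a session log click by click through the four strategy automata
#' and the hidden-Markov-style observer: at every click step the per-strategy
#' emission distributions over (mistake, explore, hit) are computed from the
#' candidate path sets, converted into transition votes, accumulated into
#' kernel-weighted transition probabilities, and the strategy weights are
#' updated by the observation-constrained Viterbi rule. Domains of action
#' update at unsuccessful trial ends and knowledge sets update as task
#' instances are learned (the advance criterion of the session
#' configuration).
#'
#' @param log A `bdt_session_log` (from [read_session_log()] or
#'   [simulate_session()]).
#' @param sigma Observation-window width in click steps; defaults to the
#'   `sigma` recorded in the log's session configuration (20 unless
#'   overridden).
#' @param init_states Optional named list of four [strategy_state()]s
#'   (names `random`, `spatial`, `generative`, `discriminative`), e.g.
#'   fully knowledgeable observers; defaults to fresh states.
#' @param keep_internals Attach per-step emissions, votes and transition
#'   matrices as attributes (`emissions`, `votes`, `transitions`) for
#'   diagnostics.
#' @return A data.frame of class `bdt_trace` with one row per click step:
#'   `step`, `task_index`, `trial_index`, `v_consensus`, `w_random`,
#'   `w_spatial`, `w_generative`, `w_discriminative`, `alpha_random`,
#'   `alpha_spatial`, `alpha_generative`, `alpha_discriminative`,
#'   `alpha_star`.
#' @export
track_session <- function(log, sigma = NULL, init_states = NULL,
                          keep_internals = FALSE) {
  res <- bdt_engine(log, sigma = sigma, init_states = init_states,
                    predict = FALSE, keep_internals = keep_internals)
  res$trace
}

#' Predict participant choices with the Mixture of Experts
#'
#' Before every click, each strategy is asked which of the two on-screen
#' icons the participant will choose: a *dichotomous* prediction when
#' exactly one of them is in the strategy's domain of action, a seeded coin
#' toss (50/50 guess) when both or neither are. The mixture prediction is
#' the action with the largest weight-summed support among dichotomous
#' experts; `guess_mass` is the total weight of the coin-tossing experts at
#' that step. Weights are those of the previous step (known before the
#' click).
#'
#' @inheritParams track_session
#' @param seed Seed for the coin-toss generator (one stream for the whole
#'   session, for exact reproducibility).
#' @return A data.frame with one row per click step: `step`,
#'   `predicted_action`, `actual_action`, `correct`, `guess_mass`.
#' @export
predict_choices <- function(log, sigma = NULL, seed = 1L, init_states = NULL) {
  res <- with_seed(seed, {
    bdt_engine(log, sigma = sigma, init_states = init_states, predict = TRUE)
  })
  res$predictions
}

# Shared engine behind track_session() / predict_choices().
bdt_engine <- function(log, sigma = NULL, init_states = NULL,
                       predict = FALSE, keep_internals = FALSE) {
  stopifnot(inherits(log, "bdt_session_log"))
  interface <- log_interface(log)
  depth <- interface$depth
  config <- log$config
  sigma <- sigma %||% config$sigma
  if (sigma <= 0) stopf("`sigma` must be positive")
  ev <- log$events
  nev <- nrow(ev)
  if (nev == 0L) stopf("empty session log")

  states <- init_states %||% stats::setNames(
    lapply(STRATEGY_KINDS, strategy_state, interface = interface),
    STRATEGY_KINDS
  )
  stopifnot(identical(names(states), STRATEGY_KINDS))
  sys_idx <- 2:4                     # spatial, generative, discriminative

  # precomputed geometry
  paths <- all_paths(depth)
  np <- length(paths)
  plocs <- vapply(paths, path_locations, character(depth))  # depth x np
  prefixes <- unique(c("", unlist(lapply(seq_len(depth - 1L),
                                         function(l) substr(paths, 1L, l)))))
  consistent <- lapply(stats::setNames(prefixes, prefixes),
                       function(p) startsWith(paths, p))

  # per-strategy cached "path fully in domain" indicator, refreshed on
  # domain changes
  path_in_D <- function(state) colSums(matrix(plocs %in% state$D,
                                              depth, np)) == depth
  pD <- lapply(states, path_in_D)

  # bookkeeping
  vote_history <- array(0, dim = c(nev, 4L, 4L))
  obs_history <- character(nev)
  click_step <- integer(nev)
  click_icon <- character(nev)
  tasks <- data.frame(task_index = integer(0), target = character(0),
                      t_start = integer(0), t_learned = integer(0),
                      stringsAsFactors = FALSE)
  w_all <- rep(1 / 4, 4L)
  w_rep <- rep(1 / 4, 4L)
  alphas <- vapply(states, alpha_gap, numeric(1))
  n_learned <- 0L

  cur_task <- NA_integer_
  cur_target <- NA_character_
  streak <- 0L

  # outputs
  tr_v <- character(nev)
  tr_w <- matrix(NA_real_, nev, 4L)
  tr_a <- matrix(NA_real_, nev, 4L)
  tr_astar <- numeric(nev)
  if (predict) {
    pr_action <- character(nev)
    pr_correct <- logical(nev)
    pr_guess <- numeric(nev)
  }
  if (keep_internals) {
    int_E <- array(NA_real_, dim = c(nev, 4L, 3L),
                   dimnames = list(NULL, STRATEGY_KINDS, OBSERVATIONS))
    int_L <- array(NA_real_, dim = c(nev, 4L, 4L),
                   dimnames = list(NULL, STRATEGY_KINDS, STRATEGY_KINDS))
  }

  targets <- log$task_targets

  for (i in seq_len(nev)) {
    task <- ev$task_index[i]
    if (is.na(cur_task) || task != cur_task) {
      cur_task <- task
      cur_target <- targets[[as.character(task)]]
      if (is.null(cur_target) || is.na(cur_target)) {
        stopf("log header lacks a target path for task %d", task)
      }
      tasks <- rbind(tasks, data.frame(
        task_index = task, target = cur_target, t_start = ev$step[i],
        t_learned = NA_integer_, stringsAsFactors = FALSE
      ))
      for (k in STRATEGY_KINDS) {
        states[[k]] <- reset_for_task(states[[k]], cur_target, interface)
      }
      pD <- lapply(states, path_in_D)
      streak <- 0L
    }

    prefix <- ev$prefix[i]
    cons <- consistent[[prefix]]
    target_open <- startsWith(cur_target, prefix)

    if (predict) {
      votes <- lapply(states, expert_prediction, context_prefix = prefix)
      mix <- mixture_predict(w_rep, votes)
      pr_action[i] <- mix$action
      pr_correct[i] <- mix$action == ev$side[i]
      pr_guess[i] <- mix$guess_mass
    }

    E <- matrix(0, 4L, 3L, dimnames = list(STRATEGY_KINDS, OBSERVATIONS))
    E[1L, ] <- c(1, 0, 0)
    for (s in sys_idx) {
      nH <- sum(pD[[s]] & cons & paths != cur_target)
      nS <- as.integer(target_open)
      E[s, ] <- if (nH > 0L || nS > 0L) {
        c(0, nH / (nH + nS), nS / (nH + nS))
      } else {
        c(1, 0, 0)
      }
    }

    # a systematic strategy whose rules cannot explain the current actions
    # (the (1,0,0) fallback) is inactive at this step: mistakes are
    # evidence for the random strategy, not for the strategy violated
    active <- c(TRUE, E[2L, 1L] == 0, E[3L, 1L] == 0, E[4L, 1L] == 0)
    l <- step_votes(E, random_index = 1L, active = active)
    vote_history[i, , ] <- l
    # Gaussian kernel support is effectively finite: weights 7.5 sigma in
    # the past are below 1e-12 of the peak, so the weighted vote average is
    # evaluated over that window only.
    from <- max(1L, i - as.integer(ceiling(7.5 * sigma)))
    win <- from:i
    tau <- kernel_weight(win, i, sigma)
    L <- matrix(colSums(matrix(vote_history[win, , , drop = FALSE],
                               nrow = length(win)) * tau) / sum(tau), 4L, 4L)
    v <- consensus_observation(E)
    obs_history[i] <- v

    upd <- tryCatch(
      update_weights(w_all, E, L, obs_history[seq_len(i)], i, sigma,
                     domains = list(NULL, states[[2L]]$D,
                                    states[[3L]]$D, states[[4L]]$D),
                     alphas = alphas, active = active),
      error = function(e) NULL
    )
    if (!is.null(upd)) {
      # steps where no strategy can explain the evidence (all costs zero)
      # leave the weights unchanged
      w_all <- upd$w_all
      w_rep <- upd$w
    }

    tr_v[i] <- v
    tr_w[i, ] <- w_rep
    tr_a[i, ] <- alphas
    tr_astar[i] <- mixed_alpha(alphas, w_rep)
    if (keep_internals) {
      int_E[i, , ] <- E
      int_L[i, , ] <- L
    }

    click_step[i] <- ev$step[i]
    click_icon[i] <- ev$icon_id[i]

    if (ev$level[i] == depth) {                 # trial boundary
      chosen <- paste0(prefix, ev$side[i])
      if (ev$feedback[i] == "pos") {
        streak <- streak + 1L
        if (streak >= config$advance_streak) {
          row <- which(tasks$task_index == cur_task)
          if (is.na(tasks$t_learned[row])) {
            tasks$t_learned[row] <- ev$step[i]
            n_learned <- n_learned + 1L
          }
        }
      } else {
        streak <- 0L
        for (s in sys_idx) states[[s]] <- update_domain(states[[s]], chosen)
        pD[sys_idx] <- lapply(states[sys_idx], path_in_D)
      }
      if (n_learned > 0L) {
        clicks <- data.frame(step = click_step[seq_len(i)],
                             icon = click_icon[seq_len(i)],
                             stringsAsFactors = FALSE)
        for (s in sys_idx) {
          states[[s]] <- update_knowledge(states[[s]], interface, tasks, clicks)
        }
        alphas <- vapply(states, alpha_gap, numeric(1))
      }
    }
  }

  trace <- data.frame(
    step = ev$step, task_index = ev$task_index, trial_index = ev$trial_index,
    v_consensus = tr_v,
    w_random = tr_w[, 1L], w_spatial = tr_w[, 2L],
    w_generative = tr_w[, 3L], w_discriminative = tr_w[, 4L],
    alpha_random = tr_a[, 1L], alpha_spatial = tr_a[, 2L],
    alpha_generative = tr_a[, 3L], alpha_discriminative = tr_a[, 4L],
    alpha_star = tr_astar, stringsAsFactors = FALSE
  )
  class(trace) <- c("bdt_trace", "data.frame")
  attr(trace, "sigma") <- sigma
  attr(trace, "tasks") <- tasks
  attr(trace, "final_alphas") <- vapply(states, alpha_gap, numeric(1))
  if (keep_internals) {
    attr(trace, "emissions") <- int_E
    attr(trace, "votes") <- vote_history
    attr(trace, "transitions") <- int_L
  }

  out <- list(trace = trace, tasks = tasks, states = states)
  if (predict) {
    out$predictions <- data.frame(
      step = ev$step, predicted_action = pr_action,
      actual_action = ev$side, correct = pr_correct,
      guess_mass = pr_guess, stringsAsFactors = FALSE
    )
  }
  out
}
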