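#' Single-strategy expert prediction
#'
#' Asks one strategy which of the two on-screen icons the participant will
#' click. The prediction is *dichotomous* when exactly one of the two
#' candidate locations is in the strategy's domain of action (that action
#' is predicted with probability 1); when both or neither are in the
#' domain, the expert is reduced to a coin toss (50/50 guess).
#'
#' @param state A [strategy_state()].
#' @param context_prefix Bit-string of the choices that reach the current
#'   screen (`""` for the first screen).
#' @return A list with `action` (`"0"` left / `"1"` right), `mode`
#'   (`"dichotomous"` or `"coin_toss"`) and `kind`.
#' @export
expert_prediction <- function(state, context_prefix) {
  stopifnot(inherits(state, "strategy_state"))
  sides <- paste0(context_prefix, c("0", "1"))
  in_dom <- sides %in% state$D
  if (sum(in_dom) == 1L) {
    list(action = substr(sides[in_dom], nchar(sides[in_dom]),
                         nchar(sides[in_dom])),
         mode = "dichotomous", kind = state$kind)
  } else {
    list(action = c("0", "1")[1L + (stats::runif(1) < 0.5)],
         mode = "coin_toss", kind = state$kind)
  }
}

#' Mixture-of-Experts next-choice prediction
#'
#' Combines per-strategy expert votes by the weighted sum rule: the support
#' for an action is the total weight of the dichotomous experts predicting
#' it, and the predicted action is the argmax (a coin toss on ties).
#' Coin-tossing experts contribute their weight to `guess_mass` and to
#' neither action's support; their random pick only decides the step when
#' all mass is coin-toss.
#'
#' @param w Normalized weight vector, one entry per expert (same order as
#'   `votes`).
#' @param votes List of [expert_prediction()] results.
#' @return A list with `action`, `support` (named mass per action) and
#'   `guess_mass`.
#' @export
mixture_predict <- function(w, votes) {
  stopifnot(length(w) == length(votes))
  mu <- c("0" = 0, "1" = 0)
  guess <- 0
  for (i in seq_along(votes)) {
    if (votes[[i]]$mode == "dichotomous") {
      mu[votes[[i]]$action] <- mu[votes[[i]]$action] + w[i]
    } else {
      guess <- guess + w[i]
    }
  }
  action <- if (mu[["0"]] > mu[["1"]]) {
    "0"
  } else if (mu[["1"]] > mu[["0"]]) {
    "1"
  } else if (guess > 0 && all(mu == 0)) {
    # fully ambiguous step: fall back on the coin toss of the heaviest
    # coin-tossing expert (all draws come from the same seeded stream)
    votes[[which.max(w)]]$action
  } else {
    c("0", "1")[1L + (stats::runif(1) < 0.5)]
  }
  list(action = action, support = mu, guess_mass = guess)
}

#' Expertise, exploration and exploitation scores of one path
#'
#' Scores a sequence of consensus observations (one per click step of a
#' chosen path): expertise averages 1 for hits, 0.5 for explorations and 0
#' for mistakes; exploration and exploitation average the respective
#' indicators. The identity
#' `expertise = exploitation + 0.5 * exploration` holds exactly.
#'
#' @param observations Character vector of consensus observations
#'   (`mistake`/`explore`/`hit`) over the path's steps.
#' @return A list with `expertise`, `exploration` and `exploitation`.
#' @export
score_path <- function(observations) {
  if (length(observations) == 0L) stopf("empty path: no observations to score")
  bad <- setdiff(unique(observations), OBSERVATIONS)
  if (length(bad)) stopf("unknown observation(s): %s", paste(bad, collapse = ", "))
  pts <- c(mistake = 0, explore = 0.5, hit = 1)
  list(
    expertise = mean(pts[observations]),
    exploration = mean(observations == "explore"),
    exploitation = mean(observations == "hit")
  )
}

#' Score every trial of a tracked session
#'
#' @param trace A `bdt_trace` from [track_session()].
#' @return A data.frame with one row per trial: `task_index`,
#'   `trial_index`, `expertise`, `exploration`, `exploitation`.
#' @export
score_paths <- function(trace) {
  stopifnot(inherits(trace, "bdt_trace"))
  key <- paste(trace$task_index, trace$trial_index)
  keys <- unique(key)
  out <- lapply(keys, function(k) {
    rows <- trace[key == k, ]
    sc <- score_path(rows$v_consensus)
    data.frame(task_index = rows$task_index[1L],
               trial_index = rows$trial_index[1L],
               expertise = sc$expertise, exploration = sc$exploration,
               exploitation = sc$exploitation)
  })
  do.call(rbind, out)
}

#' Classify a session as learner or non-learner
#'
#' A learner completes all `2^depth` task instances with consistent
#' positive feedback (every instance reaches the advance streak; none is
#' force-advanced or cut off by the session time cap).
#'
#' @param log A `bdt_session_log` covering a full session.
#' @return `"learner"` or `"non_learner"`.
#' @export
classify_participant <- function(log) {
  stopifnot(inherits(log, "bdt_session_log"))
  ev <- log$events
  depth <- log$depth
  if (nrow(ev) == 0L || nrow(ev) %% depth != 0L ||
      ev$level[nrow(ev)] != depth) {
    stopf("truncated trace: the log ends mid-trial")
  }
  n_instances <- 2L^depth
  task_ids <- unique(ev$task_index)
  if (length(task_ids) < n_instances) return("non_learner")
  streak_goal <- log$config$advance_streak
  for (task in task_ids) {
    fb <- ev$feedback[ev$task_index == task & ev$level == depth]
    runs <- rle(fb)
    if (!any(runs$values == "pos" & runs$lengths >= streak_goal)) {
      return("non_learner")
    }
  }
  "learner"
}

#' Group-average curves on a common interpolated grid
#'
#' Participants repeat each task instance a different number of trials. To
#' average per-trial curves across a group, each task gets a bin size equal
#' to the group-mean trial count for that task (rounded to at least 1);
#' every participant's per-trial vector for that task is linearly
#' interpolated onto that grid, the grids are concatenated across tasks,
#' and values are averaged pointwise with a standard error. Tasks missing
#' for a participant are averaged over the participants that have them.
#'
#' @param per_participant A list (one element per participant) of lists
#'   (one numeric vector per task, named or indexed by task).
#' @return A data.frame with `task`, `position` (grid point within task),
#'   `mean`, `se` and `n` (participants contributing).
#' @export
group_average_curves <- function(per_participant) {
  if (!length(per_participant)) stopf("no participants")
  task_names <- unique(unlist(lapply(per_participant, names)))
  if (is.null(task_names)) {
    task_names <- as.character(seq_len(max(lengths(per_participant))))
    per_participant <- lapply(per_participant, function(p) {
      stats::setNames(p, as.character(seq_along(p)))
    })
  }
  out <- list()
  for (task in task_names) {
    vecs <- lapply(per_participant, function(p) p[[task]])
    vecs <- vecs[!vapply(vecs, is.null, logical(1))]
    if (!length(vecs)) next
    bin <- max(1L, round(mean(lengths(vecs))))
    grid <- vapply(vecs, function(y) {
      n <- length(y)
      if (n == 1L) rep(y, bin)
      else if (bin == 1L) mean(y)
      else stats::approx(seq(0, 1, length.out = n), y,
                         xout = seq(0, 1, length.out = bin))$y
    }, numeric(bin))
    grid <- matrix(grid, nrow = bin)
    m <- rowMeans(grid)
    se <- if (ncol(grid) > 1L) {
      apply(grid, 1L, stats::sd) / sqrt(ncol(grid))
    } else {
      rep(0, bin)
    }
    out[[task]] <- data.frame(task = task, position = seq_len(bin),
                              mean = m, se = se, n = ncol(grid),
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
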