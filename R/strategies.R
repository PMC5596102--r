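#' Strategy automata: domains of action and knowledge sets
#'
#' Four hierarchically ordered search strategies are modeled as automata
#' over the BDT. Each keeps a *domain of action* `D` (the locations its
#' rules currently permit clicking), a *learned set* `R` (locations for the
#' spatial strategy; concept-icon pairs, keyed by icon id, for the
#' generative and discriminative strategies) and a universe `G` of
#' learnable items. The knowledge gap `alpha = 1 - |R|/|G|` is 1 with no
#' knowledge and 0 at full knowledge; the random strategy never learns and
#' has `alpha = 1` throughout.
#'
#' @param kind One of `"random"`, `"spatial"`, `"generative"`,
#'   `"discriminative"`.
#' @param interface A [build_interface()] object.
#' @param full_knowledge Start with `R = G` (a fully knowledgeable
#'   observer), used e.g. to study the exploitation limit of the
#'   Mixture-of-Experts predictor.
#' @return An object of class `strategy_state` with elements `kind`, `D`,
#'   `R`, `G`, `depth` and `active`.
#' @export
strategy_state <- function(kind, interface, full_knowledge = FALSE) {
  kind <- match.arg(kind, STRATEGY_KINDS)
  stopifnot(inherits(interface, "bdt_interface"))
  G <- switch(kind,
    random = interface$locations,
    spatial = interface$locations,
    unique(unname(interface$icon_of))   # 16 concept-icon pairs
  )
  R <- if (full_knowledge && kind != "random") G else character(0)
  structure(
    list(kind = kind, D = interface$locations, R = R, G = G,
         depth = interface$depth, active = TRUE),
    class = "strategy_state"
  )
}

#' @export
print.strategy_state <- function(x, ...) {
  cat(sprintf("<strategy_state> %s: |D| = %d, |R| = %d / |G| = %d (alpha = %.3f)\n",
              x$kind, length(x$D), length(x$R), length(x$G), alpha_gap(x)))
  invisible(x)
}

#' Knowledge gap of a strategy
#'
#' `alpha = 1 - |R|/|G|`: 1 means complete lack of knowledge about the
#' interface, 0 full knowledge. The random strategy does not learn and
#' always returns 1.
#'
#' @param state A [strategy_state()].
#' @return A number in `[0, 1]`.
#' @export
alpha_gap <- function(state) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$kind == "random") return(1)
  if (length(state$G) == 0L) stopf("strategy universe G is empty")
  1 - length(state$R) / length(state$G)
}

#' Initialize a strategy's domain of action for a task instance
#'
#' At the start of each task instance, valid actions for the systematic
#' strategies are the unexplored/unlearned locations plus every location of
#' the target path (the target is never pruned). The concept-based
#' strategies additionally discard, for every learned concept on the target
#' path, the whole subtree under that concept's on-screen neighbor. The
#' random strategy's domain is always the full tree.
#'
#' @param state A [strategy_state()].
#' @param target Target path bit-string of the task instance.
#' @param interface The interface the task belongs to.
#' @return The updated `strategy_state`.
#' @export
reset_for_task <- function(state, target, interface) {
  stopifnot(inherits(state, "strategy_state"),
            inherits(interface, "bdt_interface"))
  if (!target %in% all_paths(interface$depth)) {
    stopf("target path '%s' is not on this interface", target)
  }
  locs <- interface$locations
  tlocs <- path_locations(target)
  if (state$kind == "random") {
    state$D <- locs
    return(state)
  }
  if (state$kind == "spatial") {
    state$D <- locs[!(locs %in% state$R) | locs %in% tlocs]
    return(state)
  }
  # generative / discriminative: domain in terms of learned concept-icon pairs
  known <- interface$icon_of[locs] %in% state$R
  D <- locs[!known | locs %in% tlocs]
  ticons <- interface$icon_of[tlocs]
  for (l in seq_along(tlocs)) {
    if (ticons[[l]] %in% state$R) {
      D <- setdiff(D, loc_subtree(loc_neighbor(tlocs[[l]]), interface$depth))
    }
  }
  state$D <- D
  state
}

#' Update a strategy's domain after an unsuccessful trial
#'
#' The leaf of the chosen path leaves the domain, and bottom-up, any
#' location on the chosen path whose on-screen neighbor is already out of
#' the domain is removed together with its parent (both branches below a
#' screen being exhausted exhausts the screen). Applies to the spatial,
#' generative and discriminative strategies while the participant is still
#' searching for positive feedback; the random strategy is unchanged.
#'
#' @param state A [strategy_state()].
#' @param chosen The path bit-string selected in the trial just ended.
#' @return The updated `strategy_state`.
#' @export
update_domain <- function(state, chosen) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$kind == "random") return(state)
  depth <- state$depth
  locs <- path_locations(chosen)
  state$D <- setdiff(state$D, locs[[depth]])   # leaf always leaves D
  for (l in seq(depth, 2L)) {
    p <- locs[[l]]
    if (!(loc_neighbor(p) %in% state$D) && !(p %in% state$D)) {
      state$D <- setdiff(state$D, c(p, loc_parent(p)))
    }
  }
  state
}

#' Update a strategy's learned set from the session history
#'
#' Knowledge accrues from *learned* tasks (instances on which the advance
#' criterion was met). For the spatial strategy, each learned task's target
#' leaf enters `R`, and bottom-up, any target-path location whose neighbor
#' is already learned enters `R` together with its parent. For the
#' concept-based strategies, a concept is learned when two tasks `a`
#' (learned at step `t_a*`) and a later-started task `b` share it on their
#' target paths, its icon was never clicked between `t_a*` and `b`'s start,
#' and it was clicked during `b`. The discriminative strategy additionally
#' labels the on-screen complement of every learned concept as learned
#' (not-A inference).
#'
#' @param state A [strategy_state()].
#' @param interface The task interface.
#' @param tasks A data.frame with one row per task instance presented so
#'   far: `task_index`, `target` (path bit-string), `t_start` (global step
#'   of the task's first click) and `t_learned` (global step at which the
#'   advance criterion was met, `NA` if not/never).
#' @param clicks A data.frame of all clicks so far: `step`, `icon`.
#' @return The updated `strategy_state`.
#' @export
update_knowledge <- function(state, interface, tasks, clicks) {
  stopifnot(inherits(state, "strategy_state"))
  if (state$kind == "random") return(state)
  if (state$kind == "spatial") {
    learned <- tasks[!is.na(tasks$t_learned), , drop = FALSE]
    if (nrow(learned) == 0L) return(state)
    R <- union(state$R, substr(learned$target, 1L, state$depth))
    repeat {
      added <- FALSE
      for (tg in learned$target) {
        for (p in path_locations(tg)) {
          if (loc_neighbor(p) %in% R) {
            new <- setdiff(c(p, loc_parent(p)), c(R, NA_character_))
            if (length(new)) {
              R <- c(R, new)
              added <- TRUE
            }
          }
        }
      }
      if (!added) break
    }
    state$R <- R
    return(state)
  }
  # generative / discriminative concept learning
  learned <- tasks[!is.na(tasks$t_learned), , drop = FALSE]
  if (nrow(learned) == 0L || nrow(clicks) == 0L) return(state)
  for (ai in seq_len(nrow(learned))) {
    t_a <- learned$t_learned[[ai]]
    icons_a <- unname(interface$icon_of[path_locations(learned$target[[ai]])])
    later <- tasks[tasks$t_start > t_a, , drop = FALSE]
    for (bi in seq_len(nrow(later))) {
      t_b <- later$t_start[[bi]]
      icons_b <- unname(interface$icon_of[path_locations(later$target[[bi]])])
      shared <- setdiff(intersect(icons_a, icons_b), state$R)
      for (ic in shared) {
        steps <- clicks$step[clicks$icon == ic]
        stray <- any(steps > t_a & steps < t_b)
        seen_in_b <- any(steps >= t_b)
        if (!stray && seen_in_b) {
          state$R <- union(state$R, ic)
          if (state$kind == "discriminative") {
            state$R <- union(state$R, icon_complement(ic))
          }
        }
      }
    }
  }
  state
}

#' Enumerate candidate paths for a strategy mid-trial
#'
#' Given the clicks made so far in the current trial, enumerates all
#' root-to-leaf paths consistent with them and splits those allowed by the
#' strategy's rules into `H` (every location in the domain of action, at
#' least one off the target — exploration-compatible) and `H_star` (every
#' location on the target path — the exploitation path). The two sets are
#' disjoint by construction.
#'
#' @param state A [strategy_state()].
#' @param trial_prefix Bit-string of the clicks made so far in the trial
#'   (`""` at trial start).
#' @param target Target path bit-string of the current task.
#' @return A list with character vectors `H` and `H_star`.
#' @export
candidate_paths <- function(state, trial_prefix, target) {
  stopifnot(inherits(state, "strategy_state"))
  depth <- state$depth
  paths <- all_paths(depth)
  paths <- paths[startsWith(paths, trial_prefix)]
  tlocs <- path_locations(target)
  in_dom <- logical(length(paths))
  on_target <- logical(length(paths))
  for (i in seq_along(paths)) {
    locs <- path_locations(paths[[i]])
    in_dom[i] <- all(locs %in% state$D)
    on_target[i] <- all(locs %in% tlocs)
  }
  list(H = paths[in_dom & !on_target], H_star = paths[on_target])
}

#' Serialize / restore a strategy state
#'
#' States serialize to JSON with `kind` and sorted `D`/`R` item lists, for
#' checkpointing and fixtures.
#'
#' @param state A [strategy_state()].
#' @param json A JSON string from `strategy_state_json()`.
#' @param interface The interface the state belongs to.
#' @return `strategy_state_json()` a JSON string;
#'   `strategy_state_from_json()` the restored `strategy_state`.
#' @export
strategy_state_json <- function(state) {
  stopifnot(inherits(state, "strategy_state"))
  jsonlite::toJSON(list(kind = state$kind, D = sort(state$D),
                        R = sort(state$R)), auto_unbox = TRUE)
}

#' @rdname strategy_state_json
#' @export
strategy_state_from_json <- function(json, interface) {
  x <- jsonlite::fromJSON(json)
  st <- strategy_state(x$kind, interface)
  st$D <- as.character(x$D)
  st$R <- as.character(x$R)
  st
}
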