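#' Scripted agent policies
#'
#' An agent policy describes a synthetic participant: one of the four pure
#' strategy kinds, a `mixture` that switches kind on a schedule of task
#' indices, or a `noisy` variant with lapse probability `epsilon` (each
#' click is replaced by a uniform one with that probability). Agents apply
#' their strategy's rules as a *generative* model: at every screen they
#' click uniformly among the actions their current domain of action allows,
#' and once a task instance has yielded positive feedback they exploit
#' (repeat the target path).
#'
#' @param kind `"random"`, `"spatial"`, `"generative"`,
#'   `"discriminative"`, `"mixture"` or `"noisy"`.
#' @param epsilon Lapse probability in `[0, 1]` (default 0; 0.1 for the
#'   canonical noisy agent).
#' @param schedule For mixtures: a data.frame with increasing `task_index`
#'   and `kind` columns giving the strategy in force from that task on.
#' @param base_kind Strategy kind a `noisy` agent perturbs, and a
#'   `mixture`'s kind before its first switch.
#' @param rng_seed Seed for the agent's choice stream.
#' @return A list of class `agent_policy`.
#' @export
agent_policy <- function(kind, epsilon = if (kind == "noisy") 0.1 else 0,
                         schedule = NULL, base_kind = "discriminative",
                         rng_seed = 1L) {
  kind <- match.arg(kind, c(STRATEGY_KINDS, "mixture", "noisy"))
  if (epsilon < 0 || epsilon > 1) stopf("`epsilon` must be in [0, 1]")
  if (kind == "mixture") {
    if (is.null(schedule) || !all(c("task_index", "kind") %in% names(schedule))) {
      stopf("a mixture policy needs a schedule with task_index and kind")
    }
    if (is.unsorted(schedule$task_index, strictly = TRUE)) {
      stopf("schedule task indices must be strictly increasing")
    }
    for (k in schedule$kind) match.arg(k, STRATEGY_KINDS)
  }
  match.arg(base_kind, STRATEGY_KINDS)
  structure(list(kind = kind, epsilon = epsilon, schedule = schedule,
                 base_kind = base_kind, rng_seed = as.integer(rng_seed)),
            class = "agent_policy")
}

#' Instantiate an agent on an interface
#'
#' @param policy An [agent_policy()].
#' @param interface A [build_interface()] object.
#' @param full_knowledge Start the agent's strategy states with `R = G`
#'   (a fully knowledgeable, purely exploiting participant whose domains
#'   collapse to the target path of each task).
#' @return A list of class `bdt_agent` holding the policy and one
#'   [strategy_state()] per systematic strategy (all are maintained so a
#'   mixture can switch mid-session).
#' @export
make_agent <- function(policy, interface, full_knowledge = FALSE) {
  stopifnot(inherits(policy, "agent_policy"),
            inherits(interface, "bdt_interface"))
  structure(
    list(policy = policy, interface = interface,
         states = stats::setNames(
           lapply(STRATEGY_KINDS, strategy_state, interface = interface,
                  full_knowledge = full_knowledge),
           STRATEGY_KINDS
         )),
    class = "bdt_agent"
  )
}

active_kind <- function(policy, presentation_index) {
  kind <- switch(policy$kind,
                 mixture = policy$base_kind,
                 noisy = policy$base_kind,
                 policy$kind)
  if (policy$kind == "mixture") {
    past <- policy$schedule[policy$schedule$task_index <= presentation_index, ]
    if (nrow(past)) kind <- past$kind[nrow(past)]
  }
  kind
}

#' Simulate a full session
#'
#' Runs the complete session protocol for a scripted agent: the `2^depth`
#' task instances are presented in a seeded random order; a task advances
#' after `advance_streak` correct trials in a row; scripted agents always
#' accept advancement prompts; the session ends when all instances are done
#' or the time cap is hit. Synthetic timestamps advance by a fixed 1.5 s
#' per click. Identical seeds give byte-identical logs.
#'
#' @param agent A [make_agent()] agent (or an [agent_policy()], which is
#'   instantiated on the spot).
#' @param interface A [build_interface()] object.
#' @param config A [session_config()]; its `rng_seed` orders the task
#'   instances, the policy's `rng_seed` drives the agent's clicks.
#' @param participant_id Identifier recorded in the log.
#' @param seconds_per_click Synthetic click duration driving the session
#'   clock (default 1.5 s).
#' @return A `bdt_session_log`.
#' @export
simulate_session <- function(agent, interface = NULL,
                             config = session_config(),
                             participant_id = NULL,
                             seconds_per_click = 1.5) {
  if (inherits(agent, "agent_policy")) {
    stopifnot(inherits(interface, "bdt_interface"))
    agent <- make_agent(agent, interface)
  }
  stopifnot(inherits(agent, "bdt_agent"), inherits(config, "session_config"))
  interface <- agent$interface
  policy <- agent$policy
  depth <- interface$depth
  participant_id <- participant_id %||%
    paste0(policy$kind, "_", policy$rng_seed)

  instances <- enumerate_instructions(interface)
  order_idx <- with_seed(config$rng_seed, sample.int(length(instances)))

  paths <- all_paths(depth)
  plocs <- vapply(paths, path_locations, character(depth))

  with_seed(policy$rng_seed, {
    states <- agent$states
    n_click <- 0L
    rows <- list()
    tasks <- data.frame(task_index = integer(0), target = character(0),
                        t_start = integer(0), t_learned = integer(0),
                        stringsAsFactors = FALSE)
    click_step <- integer(0)
    click_icon <- character(0)
    task_targets <- character(0)
    session_over <- FALSE

    for (k in seq_along(order_idx)) {
      if (session_over) break
      inst <- instances[[order_idx[k]]]
      target <- inst$target
      task_targets[[as.character(k)]] <- target
      kind <- active_kind(policy, k)
      for (s in STRATEGY_KINDS) {
        states[[s]] <- reset_for_task(states[[s]], target, interface)
      }
      tasks <- rbind(tasks, data.frame(
        task_index = k, target = target, t_start = n_click + 1L,
        t_learned = NA_integer_, stringsAsFactors = FALSE
      ))
      st <- new_session_state()
      trial <- 0L
      exploit <- FALSE

      repeat {
        trial <- trial + 1L
        prefix <- ""
        D <- states[[kind]]$D
        # paths the active strategy's rules currently allow: fully
        # in-domain completions plus the target (the target path is never
        # pruned by the strategy rules)
        viable <- colSums(matrix(plocs %in% D, depth, length(paths))) == depth
        viable <- viable | paths == target
        for (l in seq_len(depth)) {
          sides <- paste0(prefix, c("0", "1"))
          side <- if (policy$epsilon > 0 && stats::runif(1) < policy$epsilon) {
            sample(c("0", "1"), 1L)
          } else if (exploit) {
            substr(target, l, l)
          } else {
            open <- c("0", "1")[vapply(sides, function(s) {
              any(viable & startsWith(paths, s))
            }, logical(1))]
            if (!length(open)) open <- c("0", "1")
            if (length(open) == 1L) open else sample(open, 1L)
          }
          prefix <- paste0(prefix, side)
          n_click <- n_click + 1L
          rows[[n_click]] <- data.frame(
            participant_id = participant_id, task_index = k,
            trial_index = trial, step = n_click, level = l,
            prefix = substr(prefix, 1L, l - 1L), side = side,
            icon_id = unname(interface$icon_of[prefix]),
            feedback = "", timestamp_ms = n_click * seconds_per_click * 1000,
            stringsAsFactors = FALSE
          )
          click_step[n_click] <- n_click
          click_icon[n_click] <- unname(interface$icon_of[prefix])
        }
        fb <- evaluate_feedback(prefix, target)
        rows[[n_click]]$feedback <- fb
        if (fb == "pos") {
          # a random policy is memoryless; systematic agents switch to
          # exploiting the found path
          if (kind != "random") exploit <- TRUE
        } else {
          for (s in setdiff(STRATEGY_KINDS, "random")) {
            states[[s]] <- update_domain(states[[s]], prefix)
          }
        }
        elapsed <- n_click * seconds_per_click / 60
        adv <- advance_session(st, fb, elapsed, config)
        st <- adv$state
        if (adv$action == "prompt_user") {
          adv <- session_prompt_response(st, accept = TRUE, config)
          st <- adv$state
        }
        if (adv$action == "advance_task") {
          row <- nrow(tasks)
          if (isTRUE(st$completed)) {
            tasks$t_learned[row] <- n_click
            clicks <- data.frame(step = click_step, icon = click_icon,
                                 stringsAsFactors = FALSE)
            for (s in setdiff(STRATEGY_KINDS, "random")) {
              states[[s]] <- update_knowledge(states[[s]], interface,
                                              tasks, clicks)
            }
          }
          break
        }
        if (adv$action == "end_session") {
          session_over <- TRUE
          break
        }
      }
    }

    events <- do.call(rbind, rows)
    new_session_log(events, interface$seed, depth, config, participant_id,
                    task_targets, vocab = interface$vocab)
  })
}

#' Generate the canonical fixture suite
#'
#' Writes one simulated session log per canonical agent — the four pure
#' strategies, one spatial-to-discriminative mixture, and one noisy
#' discriminative agent with `epsilon = 0.1` — plus a JSON manifest of the
#' generating policies. Re-running with the same seeds reproduces identical
#' files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seeds Two integers: the agents' click seed and the task-order
#'   seed.
#' @param config Session configuration shared by all agents.
#' @param interface_seed Seed of the shared interface.
#' @return Invisibly, the manifest as a data.frame (`file`, `kind`,
#'   `epsilon`).
#' @export
generate_fixture_suite <- function(out_dir, seeds = c(1L, 1L),
                                   config = NULL, interface_seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  config <- config %||% session_config(rng_seed = seeds[2L])
  interface <- build_interface(seed = interface_seed)
  policies <- list(
    agent_policy("random", rng_seed = seeds[1L]),
    agent_policy("spatial", rng_seed = seeds[1L]),
    agent_policy("generative", rng_seed = seeds[1L]),
    agent_policy("discriminative", rng_seed = seeds[1L]),
    agent_policy("mixture",
                 schedule = data.frame(task_index = 5L,
                                       kind = "discriminative"),
                 base_kind = "spatial", rng_seed = seeds[1L]),
    agent_policy("noisy", base_kind = "discriminative", rng_seed = seeds[1L])
  )
  manifest <- list()
  for (p in policies) {
    file <- file.path(out_dir, paste0(p$kind, ".csv"))
    log <- simulate_session(p, interface, config)
    write_session_log(log, file)
    manifest[[length(manifest) + 1L]] <- list(
      file = basename(file), kind = p$kind, epsilon = p$epsilon,
      base_kind = p$base_kind,
      schedule = if (!is.null(p$schedule)) p$schedule else NULL,
      seeds = list(agent = p$rng_seed, task_order = config$rng_seed,
                   interface = interface_seed)
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(do.call(rbind, lapply(manifest, function(m) {
    data.frame(file = m$file, kind = m$kind, epsilon = m$epsilon,
               stringsAsFactors = FALSE)
  })))
}
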