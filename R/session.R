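#' Session protocol configuration
#'
#' Parameters of the experimental session protocol: a task instance is
#' repeated until the participant chooses the correct path
#' `advance_streak` times in a row; after `prompt_after_wrong` successive
#' wrong answers the participant is asked whether to move on; if they
#' refuse, they are asked again after `second_prompt_after` further wrong
#' answers; if they persist they get `final_chances` additional trials
#' before being force-advanced. The whole session is capped at
#' `max_minutes`. `sigma` is the Gaussian observation-window width of the
#' behavioral model, in click steps.
#'
#' @param advance_streak Consecutive correct trials required to advance
#'   (default 5).
#' @param prompt_after_wrong Successive wrong answers before the first
#'   prompt (default 15).
#' @param second_prompt_after Further wrong answers before the second
#'   prompt (default 10).
#' @param final_chances Trials granted after persisting past the second
#'   prompt (default 5).
#' @param max_minutes Session time cap in minutes (default 40).
#' @param sigma Observation-window width in click steps (default 20).
#' @param rng_seed Integer seed recorded with the session.
#' @return A list of class `session_config`.
#' @export
session_config <- function(advance_streak = 5L, prompt_after_wrong = 15L,
                           second_prompt_after = 10L, final_chances = 5L,
                           max_minutes = 40, sigma = 20, rng_seed = 1L) {
  cfg <- list(advance_streak = as.integer(advance_streak),
              prompt_after_wrong = as.integer(prompt_after_wrong),
              second_prompt_after = as.integer(second_prompt_after),
              final_chances = as.integer(final_chances),
              max_minutes = as.numeric(max_minutes),
              sigma = as.numeric(sigma),
              rng_seed = as.integer(rng_seed))
  for (f in c("advance_streak", "prompt_after_wrong", "second_prompt_after",
              "final_chances")) {
    if (!is_count(cfg[[f]])) stopf("`%s` must be a positive integer", f)
  }
  if (cfg$max_minutes <= 0) stopf("`max_minutes` must be positive")
  if (cfg$sigma <= 0) stopf("`sigma` must be positive")
  class(cfg) <- "session_config"
  cfg
}

#' Read a session configuration from YAML
#'
#' The YAML keys mirror [session_config()] argument names exactly; absent
#' keys take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(session_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(session_config, vals)
}

#' Session progress state machine
#'
#' Tracks per-task streaks and wrong-answer counts and decides, after each
#' trial, whether to continue, advance to the next task, prompt the
#' participant, force-advance, or end the session.
#'
#' `new_session_state()` starts a fresh per-task state.
#' `advance_session()` consumes one trial result and returns the updated
#' state plus an `action` in `continue`, `advance_task`, `prompt_user`,
#' `force_advance`, `end_session`. When the action is `prompt_user`,
#' [session_prompt_response()] must be called with the participant's
#' decision before the next trial.
#'
#' @param state A session state as returned by `new_session_state()` or a
#'   previous call.
#' @param trial_result `"pos"` or `"neg"`.
#' @param elapsed_minutes Minutes elapsed since session start.
#' @param config A [session_config()].
#' @return A list with the updated `state` and the `action` string.
#' @export
new_session_state <- function() {
  list(streak = 0L, wrongs = 0L, stage = 0L, chances_left = NA_integer_,
       completed = NA)
}

#' @rdname new_session_state
#' @export
advance_session <- function(state, trial_result, elapsed_minutes, config) {
  stopifnot(inherits(config, "session_config"))
  if (elapsed_minutes >= config$max_minutes) {
    return(list(state = state, action = "end_session"))
  }
  if (trial_result == "pos") {
    state$streak <- state$streak + 1L
    state$wrongs <- 0L
    state$stage <- 0L
    state$chances_left <- NA_integer_
    if (state$streak >= config$advance_streak) {
      state$completed <- TRUE
      return(list(state = state, action = "advance_task"))
    }
    return(list(state = state, action = "continue"))
  }
  # negative feedback
  state$streak <- 0L
  state$wrongs <- state$wrongs + 1L
  if (state$stage == 2L) {
    state$chances_left <- state$chances_left - 1L
    if (state$chances_left <= 0L) {
      state$completed <- FALSE
      return(list(state = state, action = "force_advance"))
    }
    return(list(state = state, action = "continue"))
  }
  if (state$stage == 0L && state$wrongs >= config$prompt_after_wrong) {
    return(list(state = state, action = "prompt_user"))
  }
  if (state$stage == 1L &&
      state$wrongs >= config$prompt_after_wrong + config$second_prompt_after) {
    return(list(state = state, action = "prompt_user"))
  }
  list(state = state, action = "continue")
}

#' @rdname new_session_state
#' @param accept Whether the participant accepts moving on to the next task.
#' @export
session_prompt_response <- function(state, accept, config) {
  stopifnot(inherits(config, "session_config"))
  if (accept) {
    state$completed <- FALSE
    return(list(state = state, action = "advance_task"))
  }
  if (state$stage == 0L) {
    state$stage <- 1L                       # refused the first prompt
  } else {
    state$stage <- 2L                       # persisted past the second
    state$chances_left <- config$final_chances
  }
  list(state = state, action = "continue")
}

# ---- session logs ----------------------------------------------------------

LOG_COLUMNS <- c("participant_id", "task_index", "trial_index", "step",
                 "level", "prefix", "side", "icon_id", "feedback",
                 "timestamp_ms")

new_session_log <- function(events, interface_seed, depth, config,
                            participant_id, task_targets, vocab = NULL) {
  structure(
    list(events = events, interface_seed = as.integer(interface_seed),
         depth = as.integer(depth), config = config,
         participant_id = participant_id,
         task_targets = task_targets, vocab = vocab),
    class = "bdt_session_log"
  )
}

#' @export
print.bdt_session_log <- function(x, ...) {
  cat(sprintf("<bdt_session_log> participant %s: %d clicks, %d tasks (depth %d, interface seed %d)\n",
              x$participant_id, nrow(x$events),
              length(unique(x$events$task_index)), x$depth, x$interface_seed))
  invisible(x)
}

#' Rebuild the interface a log was recorded on
#'
#' @param log A `bdt_session_log`.
#' @return The [build_interface()] object reconstructed from the seed (and
#'   vocabulary) stored in the log header.
#' @export
log_interface <- function(log) {
  stopifnot(inherits(log, "bdt_session_log"))
  vocab <- log$vocab %||% default_vocab(log$depth)
  build_interface(log$depth, vocab, log$interface_seed)
}

validate_log_events <- function(events, depth) {
  miss <- setdiff(LOG_COLUMNS, names(events))
  if (length(miss)) stopf("missing required column(s): %s", paste(miss, collapse = ", "))
  if (nrow(events) == 0L) return(invisible(events))
  if (any(diff(events$step) <= 0L)) {
    row <- which(diff(events$step) <= 0L)[1L] + 1L
    stopf("parse error at row %d: steps must strictly increase", row)
  }
  bad_fb <- which(events$feedback != "" & events$level != depth)
  if (length(bad_fb)) {
    stopf("parse error at row %d: feedback on a non-leaf click", bad_fb[1L])
  }
  no_fb <- which(events$feedback == "" & events$level == depth)
  if (length(no_fb)) {
    stopf("parse error at row %d: leaf click without feedback", no_fb[1L])
  }
  # within-trial consecutive consistency
  key <- paste(events$task_index, events$trial_index)
  for (k in unique(key)) {
    idx <- which(key == k)
    ev <- events[idx, ]
    if (any(ev$level != seq_len(nrow(ev)))) {
      stopf("parse error at row %d: trial levels out of order", idx[1L])
    }
    locs <- paste0(ev$prefix, ev$side)
    if (nrow(ev) > 1L &&
        any(locs[-nrow(ev)] != ev$prefix[-1L])) {
      row <- idx[1L + which(locs[-nrow(ev)] != ev$prefix[-1L])[1L]]
      stopf("parse error at row %d: choices do not form a consistent path", row)
    }
  }
  invisible(events)
}

log_header <- function(log) {
  list(interface_seed = log$interface_seed, depth = log$depth,
       participant_id = log$participant_id,
       config = unclass(log$config),
       task_targets = as.list(log$task_targets))
}

header_to_log <- function(header, events) {
  cfg <- do.call(session_config, header$config)
  targets <- unlist(header$task_targets)
  validate_log_events(events, header$depth)
  new_session_log(events, header$interface_seed, header$depth, cfg,
                  header$participant_id, targets)
}

#' Write / read session logs
#'
#' Logs are stored either as CSV (columns
#' `participant_id,task_index,trial_index,step,level,prefix,side,icon_id,feedback,timestamp_ms`,
#' with feedback blank except on leaf clicks) plus a JSON sidecar
#' `<path>.json` holding the interface seed, session configuration and
#' per-task target paths, or as JSONL where the first line is that header
#' object and each subsequent line is one click event. `read_session_log()`
#' restores a log field-for-field; the header makes a log self-describing
#' (the interface can be rebuilt from its seed).
#'
#' @param log A `bdt_session_log`.
#' @param path Output/input file; `.jsonl` selects the JSONL dialect,
#'   anything else CSV.
#' @return `read_session_log()` returns the `bdt_session_log`;
#'   `write_session_log()` returns `path` invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "bdt_session_log"))
  validate_log_events(log$events, log$depth)
  header <- log_header(log)
  if (grepl("\\.jsonl$", path)) {
    lines <- c(
      jsonlite::toJSON(header, auto_unbox = TRUE),
      vapply(seq_len(nrow(log$events)), function(i) {
        as.character(jsonlite::toJSON(as.list(log$events[i, ]), auto_unbox = TRUE))
      }, character(1))
    )
    writeLines(lines, path)
  } else {
    utils::write.csv(log$events, path, row.names = FALSE, quote = TRUE)
    jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path)
    if (length(lines) < 1L) stopf("empty log file: %s", path)
    header <- jsonlite::fromJSON(lines[1L], simplifyVector = TRUE)
    if (length(lines) > 1L) {
      rows <- lapply(seq_along(lines[-1L]), function(i) {
        ev <- tryCatch(jsonlite::fromJSON(lines[i + 1L]),
                       error = function(e) stopf("parse error at row %d: %s", i, conditionMessage(e)))
        as.data.frame(ev, stringsAsFactors = FALSE)
      })
      events <- do.call(rbind, rows)
    } else {
      events <- empty_events()
    }
  } else {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) stopf("missing log header sidecar: %s", sidecar)
    header <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    events <- utils::read.csv(path, colClasses = c(
      participant_id = "character", task_index = "integer",
      trial_index = "integer", step = "integer", level = "integer",
      prefix = "character", side = "character", icon_id = "character",
      feedback = "character", timestamp_ms = "numeric"
    ), na.strings = character(0))
  }
  events$prefix <- as.character(events$prefix)
  events$side <- as.character(events$side)
  events$feedback <- as.character(events$feedback)
  header_to_log(header, events)
}

empty_events <- function() {
  data.frame(participant_id = character(0), task_index = integer(0),
             trial_index = integer(0), step = integer(0), level = integer(0),
             prefix = character(0), side = character(0),
             icon_id = character(0), feedback = character(0),
             timestamp_ms = numeric(0), stringsAsFactors = FALSE)
}
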