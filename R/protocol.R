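#' Build the offline AO+MI pre-training protocol
#'
#' Schedules the offline acquisition runs. Each run presents the three
#' movement classes in three sets each (nine sets per run); within a set, two
#' action-observation + motor-imagery (AO+MI) trials precede one pure MI
#' trial, so one run holds 27 trials (9 per movement class, 6 AO+MI + 3 MI).
#' Fifteen runs thus give the canonical 90 AO+MI and 45 pure-MI trials per
#' class. Set order is randomized per run under `seed`.
#'
#' Each trial is a fixation/rest period drawn uniformly from 4-5 s, a 1 s
#' preparatory interval, a 3 s movement (imagery) period, and a 1 s post
#' interval; `onset` is the movement-period onset, which is also the event
#' trigger written by [synthesize_recording()].
#'
#' @param n_runs number of runs (>= 1).
#' @param seed integer seed controlling set order and rest durations.
#' @param classes movement classes (default left hand, right hand, both feet).
#' @return a `protocol_plan` data.frame, one row per trial, with columns
#'   `trial_id`, `run`, `class`, `kind` (`"AO+MI"` or `"MI"`), `rest_s`,
#'   `prep_s`, `move_s`, `post_s`, `onset`, `t_start`, `t_end`. Timestamps are
#'   strictly increasing and trials never overlap.
#' @export
build_offline_protocol <- function(n_runs, seed = 1L,
                                   classes = SMR_MOVEMENT_CLASSES) {
  if (!is.numeric(n_runs) || length(n_runs) != 1 || n_runs < 1) {
    stop("n_runs must be a positive integer")
  }
  n_runs <- as.integer(n_runs)
  with_seed(seed, {
    rows <- list()
    t_cursor <- 0
    trial_id <- 0L
    for (run in seq_len(n_runs)) {
      sets <- rep(classes, each = 3)            # 3 sets per class
      sets <- sample(sets)                      # randomized set order
      for (cls in sets) {
        kinds <- c("AO+MI", "AO+MI", "MI")      # fixed order within a set
        for (kind in kinds) {
          trial_id <- trial_id + 1L
          rest_s <- runif(1, 4, 5)
          prep_s <- 1; move_s <- 3; post_s <- 1
          onset <- t_cursor + rest_s + prep_s
          rows[[trial_id]] <- data.frame(
            trial_id = trial_id, run = run, class = cls, kind = kind,
            rest_s = rest_s, prep_s = prep_s, move_s = move_s, post_s = post_s,
            onset = onset, t_start = t_cursor,
            t_end = onset + move_s + post_s,
            stringsAsFactors = FALSE)
          t_cursor <- onset + move_s + post_s
        }
      }
    }
    plan <- do.call(rbind, rows)
    class(plan) <- c("protocol_plan", class(plan))
    attr(plan, "protocol") <- "offline"
    plan
  })
}

#' Build the online feedback protocol
#'
#' Schedules closed-loop maze-navigation trials. Each trial begins with a
#' fixation cross of random 2-3 s duration, then up to `max_attempts`
#' attempts; each attempt is a 1 s preparatory interval, a 2 s directional
#' cue (imagery phase), and a 4 s classification window. A failed attempt is
#' followed immediately by the next attempt's 1 s preparation; after
#' `max_attempts` failures the trial is force-passed.
#'
#' The plan is attempt-level: one row per (trial, attempt) with the cue onset
#' of that attempt, so the simulator can modulate rhythms during every cued
#' imagery window and the session runner can consume attempts in order.
#'
#' @param n_trials number of cue trials.
#' @param seed integer seed for cue order and fixation durations.
#' @param classes movement classes to cue (balanced, shuffled).
#' @param max_attempts retry limit per instruction (default 3).
#' @return a `protocol_plan` data.frame with columns `trial_id`, `attempt`,
#'   `class`, `kind` (`"online"`), `fix_s`, `prep_s`, `cue_s`, `window_s`,
#'   `onset` (cue onset of the attempt), `t_start`, `t_end`.
#' @export
build_online_protocol <- function(n_trials, seed = 1L,
                                  classes = SMR_MOVEMENT_CLASSES,
                                  max_attempts = 3L) {
  if (!is.numeric(n_trials) || length(n_trials) != 1 || n_trials < 1) {
    stop("n_trials must be a positive integer")
  }
  n_trials <- as.integer(n_trials)
  with_seed(seed, {
    cues <- rep(classes, length.out = n_trials)
    cues <- sample(cues)
    rows <- list()
    t_cursor <- 0
    k <- 0L
    for (i in seq_len(n_trials)) {
      fix_s <- runif(1, 2, 3)
      prep_s <- 1; cue_s <- 2; window_s <- 4
      t_start <- t_cursor
      for (a in seq_len(max_attempts)) {
        k <- k + 1L
        onset <- t_start + fix_s + prep_s + (a - 1) * (prep_s + cue_s + window_s)
        rows[[k]] <- data.frame(
          trial_id = i, attempt = a, class = cues[i], kind = "online",
          fix_s = fix_s, prep_s = prep_s, cue_s = cue_s, window_s = window_s,
          onset = onset, t_start = t_start,
          t_end = t_start + fix_s + max_attempts * (prep_s + cue_s + window_s) + 1,
          stringsAsFactors = FALSE)
      }
      t_cursor <- rows[[k]]$t_end
    }
    plan <- do.call(rbind, rows)
    class(plan) <- c("protocol_plan", class(plan))
    attr(plan, "protocol") <- "online"
    plan
  })
}
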