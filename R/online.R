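#' Temporal smoothing of a prediction stream
#'
#' A command is confirmed only after `required` identical consecutive
#' non-rest predictions (predictions arrive every 0.1 s, so the default 5
#' adds about 0.5 s of latency); otherwise the output defaults to rest. The
#' first qualifying run wins; the confirmation index is the position of the
#' run's `required`-th element.
#'
#' @param predictions character vector of per-window predictions, time
#'   ordered.
#' @param required run length needed to confirm (default 5).
#' @param rest_label the idle class (default `"rest"`).
#' @return list with `command` (a class label, or `rest_label` if no run
#'   qualified) and `index` (confirmation position, NA if none).
#' @export
smooth_decode <- function(predictions, required = 5, rest_label = "rest") {
  n <- length(predictions)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (i > 1 && predictions[i] == predictions[i - 1]) run + 1L else 1L
    if (run >= required && predictions[i] != rest_label) {
      return(list(command = predictions[i], index = i))
    }
  }
  list(command = rest_label, index = NA_integer_)
}

# fixed-start windows at explicit start times
windows_at <- function(recording, start_times, window_s) {
  fs <- recording$sampling_rate
  win <- round(window_s * fs)
  n <- length(start_times)
  dat <- array(0, dim = c(nrow(recording$signal), win, n))
  for (i in seq_len(n)) {
    s0 <- floor(start_times[i] * fs) + 1L
    dat[, , i] <- recording$signal[, s0:(s0 + win - 1)]
  }
  epoch_set(dat, rep(NA_character_, n), fs, recording$channel_names,
            data.frame(trial_id = rep(NA_integer_, n),
                       kind = rep("window", n),
                       t0 = start_times, offset_s = rep(0, n)))
}

#' Sliding-window predictions over a stream span
#'
#' Emits one prediction per `step_s` over `(t_from, t_to]`, each based on
#' the trailing `window_s` seconds of the (causally filtered) stream,
#' decimated to the model's epoch rate and normalized with the checkpoint's
#' statistics.
#'
#' @param model a `conformer_model` with `norm_stats`, or a function
#'   mapping an [epoch_set()] of raw windows to a label vector (useful for
#'   testing the trial logic with scripted decoders).
#' @param stream a causally filtered [eeg_recording()].
#' @param t_from,t_to span of prediction times in seconds.
#' @param window_s,step_s sliding-window geometry (defaults 2 and 0.1 s).
#' @return data.frame with columns `time` (prediction timestamp = window
#'   end) and `prediction`.
#' @export
decode_stream <- function(model, stream, t_from, t_to,
                          window_s = 2, step_s = 0.1) {
  ends <- seq(t_from + step_s, t_to + 1e-9, by = step_s)
  starts <- ends - window_s
  ok <- starts >= 0 & ends <= recording_duration(stream) + 1e-9
  starts <- starts[ok]; ends <- ends[ok]
  if (length(starts) == 0) {
    return(data.frame(time = numeric(0), prediction = character(0)))
  }
  eps <- windows_at(stream, starts, window_s)
  if (is.function(model)) {
    labels <- model(eps)
  } else {
    target_rate <- model$config$n_samples / window_s
    eps <- downsample_epochs(eps, target_rate)
    labels <- predict_classes(model, eps)
  }
  data.frame(time = ends, prediction = labels, stringsAsFactors = FALSE)
}

#' Run one closed-loop online trial
#'
#' Consumes the trial's attempts in order. Each attempt opens a 4 s
#' classification window after the 2 s cue phase; sliding-window
#' predictions are smoothed ([smooth_decode()]) with the run counter reset
#' at each attempt. A confirmed command equal to the cue succeeds the trial
#' and timestamps the motion onset; a mismatch or rest leads to the next
#' attempt after its 1 s preparation, and after `max_attempts` failures the
#' trial is force-passed.
#'
#' @param model a `conformer_model` with `norm_stats`.
#' @param stream the causally filtered session [eeg_recording()].
#' @param trial_plan the attempt-level plan rows of one trial (from
#'   [build_online_protocol()]).
#' @param required smoothing run length (default 5).
#' @return a `trial_outcome` list: `cue`, `attempts` (1..max), `success`,
#'   `force_passed`, `cue_onset` (first attempt), `motion_onset` (NA unless
#'   success).
#' @export
run_online_trial <- function(model, stream, trial_plan, required = 5) {
  trial_plan <- trial_plan[order(trial_plan$attempt), , drop = FALSE]
  cue <- trial_plan$class[1]
  n_att <- nrow(trial_plan)
  outcome <- list(cue = cue, attempts = n_att, success = FALSE,
                  force_passed = FALSE,
                  cue_onset = trial_plan$onset[1],
                  motion_onset = NA_real_)
  for (a in seq_len(n_att)) {
    row <- trial_plan[a, ]
    w0 <- row$onset + row$cue_s
    if (w0 + row$window_s > recording_duration(stream) + 1e-9) {
      stop("stream ends before the classification window of trial ",
           row$trial_id, ", attempt ", a)
    }
    preds <- decode_stream(model, stream, w0, w0 + row$window_s)
    sm <- smooth_decode(preds$prediction, required)
    if (sm$command == cue) {
      outcome$success <- TRUE
      outcome$attempts <- a
      outcome$motion_onset <- preds$time[sm$index]
      return(structure(outcome, class = "trial_outcome"))
    }
  }
  outcome$force_passed <- TRUE
  structure(outcome, class = "trial_outcome")
}

#' Run a full online feedback session
#'
#' Causally filters the session recording (8-30 Hz, third-order
#' Butterworth) and runs every trial through [run_online_trial()].
#'
#' @param model a `conformer_model` with `norm_stats`.
#' @param recording the raw session [eeg_recording()] whose events carry the
#'   attempt-level plan.
#' @param plan the session's attempt-level `protocol_plan`.
#' @param required smoothing run length (default 5).
#' @return list with `outcomes` (one `trial_outcome` per trial) and
#'   `command_accuracy` (% of trials succeeded, force-passes counted as
#'   failures).
#' @export
run_online_session <- function(model, recording, plan, required = 5) {
  stream <- online_filter(recording)
  if (inherits(model, "conformer_model")) {
    target <- model$config$n_samples / 2      # 2 s decoding windows
    if (target != stream$sampling_rate) {
      stream <- downsample_recording(stream, target)
    }
  }
  ids <- unique(plan$trial_id)
  outcomes <- lapply(ids, function(id) {
    run_online_trial(model, stream, plan[plan$trial_id == id, , drop = FALSE],
                     required)
  })
  list(outcomes = outcomes,
       command_accuracy = 100 * mean(vapply(outcomes, `[[`, TRUE, "success")))
}

#' Label a session's epochs from its trial outcomes
#'
#' Successful trials anchor the imagery trigger 2.5 s before the confirmed
#' motion onset; failed (force-passed) trials assume imagery began at cue
#' presentation and anchor at the first cue onset. Each trial then yields
#' `spec$n_segments` overlapping 2 s segments at 0.1 s offsets labeled with
#' the cue class, plus rest segments anchored 3 s before the cue. Anchors
#' outside the recording are skipped with a warning.
#'
#' @param outcomes list of `trial_outcome`s from [run_online_session()].
#' @param recording the *offline-chain filtered* session recording (the
#'   training-data path).
#' @param spec an [augmentation_spec()].
#' @return an [epoch_set()] (unbalanced; balancing happens in
#'   [adapt_model()]).
#' @export
label_session <- function(outcomes, recording, spec = augmentation_spec()) {
  if (length(outcomes) == 0) {
    d <- round(spec$segment_s * recording$sampling_rate)
    return(epoch_set(array(0, c(nrow(recording$signal), d, 0)),
                     character(0), recording$sampling_rate,
                     recording$channel_names))
  }
  anchors <- vapply(outcomes, function(o) {
    if (o$success) o$motion_onset - 2.5 else o$cue_onset
  }, numeric(1))
  cues <- vapply(outcomes, `[[`, "", "cue")
  cue_onsets <- vapply(outcomes, `[[`, 0, "cue_onset")
  mi_ev <- data.frame(onset = anchors, code = NA_integer_, class = cues,
                      kind = "online", trial_id = seq_along(outcomes))
  rest_ev <- data.frame(onset = cue_onsets, code = NA_integer_, class = cues,
                        kind = "online", trial_id = seq_along(outcomes))
  pieces <- list()
  for (i in seq_len(spec$n_segments)) {
    off <- (i - 1) * spec$step_s
    pieces[[i]] <- suppressWarnings(
      extract_epochs(recording, spec$segment_s, off, events = mi_ev))
    pieces[[spec$n_segments + i]] <- suppressWarnings(
      extract_epochs(recording, spec$segment_s, spec$rest_offset_s + off,
                     events = rest_ev, label = "rest"))
  }
  do.call(bind_epochs, pieces)
}
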