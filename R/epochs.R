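#' Fixed-length labeled epochs
#'
#' An `epoch_set` stores per-trial windows as a channels x samples x n array
#' plus labels and provenance (source trial, trigger-relative start, segment
#' offset). Windows are expressed in seconds, 0-based and half-open
#' `[t0, t0 + window)`.
#'
#' @param data numeric array, channels x samples x n.
#' @param labels character/factor vector of length n (may be NA for
#'   unlabeled sliding windows).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names channel labels.
#' @param meta data.frame of per-epoch provenance (`trial_id`, `kind`, `t0`,
#'   `offset_s`).
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, sampling_rate, channel_names,
                      meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  n <- dim(data)[3]
  if (length(labels) != n) stop("labels must have one entry per epoch")
  if (is.null(meta)) {
    meta <- data.frame(trial_id = rep(NA_integer_, n),
                       kind = rep(NA_character_, n),
                       t0 = rep(NA_real_, n),
                       offset_s = rep(NA_real_, n))
  }
  structure(list(data = data, labels = as.character(labels),
                 sampling_rate = sampling_rate,
                 channel_names = channel_names, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %d channels x %d samples @ %g Hz\n",
              n_epochs(x), dim(x$data)[1], dim(x$data)[2], x$sampling_rate))
  if (!all(is.na(x$labels))) print(table(x$labels))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs an [epoch_set()].
#' @export
n_epochs <- function(epochs) dim(epochs$data)[3]

#' Subset an epoch set
#' @param epochs an [epoch_set()].
#' @param idx integer or logical index over epochs.
#' @export
subset_epochs <- function(epochs, idx) {
  epoch_set(epochs$data[, , idx, drop = FALSE], epochs$labels[idx],
            epochs$sampling_rate, epochs$channel_names,
            epochs$meta[idx, , drop = FALSE])
}

#' Concatenate epoch sets
#' @param ... [epoch_set()] objects with identical geometry.
#' @export
bind_epochs <- function(...) {
  sets <- Filter(function(e) !is.null(e) && n_epochs(e) > 0, list(...))
  if (length(sets) == 0) stop("nothing to bind")
  ref <- sets[[1]]
  dat <- array(unlist(lapply(sets, function(e) e$data), use.names = FALSE),
               dim = c(dim(ref$data)[1], dim(ref$data)[2],
                       sum(vapply(sets, n_epochs, 1L))))
  epoch_set(dat, unlist(lapply(sets, `[[`, "labels")),
            ref$sampling_rate, ref$channel_names,
            do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Save / load an epoch set as a single-file container
#'
#' Serializes the windows together with their labels, sampling rate,
#' channel names and provenance metadata; the round-trip is exact.
#'
#' @param epochs an [epoch_set()].
#' @param path file path.
#' @return `read_epochs` returns the restored [epoch_set()].
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  epochs <- readRDS(path)
  if (!inherits(epochs, "epoch_set")) {
    stop("not an epoch-set container: ", path)
  }
  epochs
}

#' Segment a recording into event-aligned epochs
#'
#' Cuts one fixed-length window per (event, offset) pair: the window starts
#' at `onset + offset_s` and spans `window_s` seconds, half-open in samples.
#' At 1000 Hz a 2 s window holds exactly 2000 samples. Windows that would
#' fall outside the recording are skipped with a warning, not an error.
#'
#' @param recording an [eeg_recording()].
#' @param window_s window length in seconds (default 2).
#' @param offset_s trigger-relative start in seconds (default 0; e.g. -3 for
#'   rest segments anchored 3 s before the event).
#' @param events event table to use (defaults to the recording's own).
#' @param label optional label overriding the events' `class` column (e.g.
#'   `"rest"` for pre-trigger baseline segments).
#' @return an [epoch_set()].
#' @export
extract_epochs <- function(recording, window_s = 2, offset_s = 0,
                           events = recording$events, label = NULL) {
  fs <- recording$sampling_rate
  n_samp <- round(window_s * fs)
  total <- ncol(recording$signal)
  keep <- logical(nrow(events))
  starts <- integer(nrow(events))
  for (i in seq_len(nrow(events))) {
    s0 <- floor((events$onset[i] + offset_s) * fs) + 1L  # 1-based sample index
    if (s0 >= 1 && s0 + n_samp - 1 <= total) {
      keep[i] <- TRUE
      starts[i] <- s0
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " window(s) fell outside the recording and were skipped")
  }
  events <- events[keep, , drop = FALSE]
  starts <- starts[keep]
  n <- length(starts)
  dat <- array(0, dim = c(nrow(recording$signal), n_samp, n))
  for (i in seq_len(n)) {
    dat[, , i] <- recording$signal[, starts[i]:(starts[i] + n_samp - 1)]
  }
  labels <- if (!is.null(label)) rep(label, n) else events$class
  meta <- data.frame(
    trial_id = if ("trial_id" %in% names(events)) events$trial_id else rep(NA_integer_, n),
    kind = if ("kind" %in% names(events)) events$kind else rep(NA_character_, n),
    t0 = (starts - 1) / fs,
    offset_s = rep(offset_s, n))
  epoch_set(dat, labels, fs, recording$channel_names, meta)
}

#' Cut a stream into overlapping sliding windows
#'
#' Produces one window per step: 2 s windows every 0.1 s overlap by 1.9 s. A
#' stream shorter than one window yields an empty sequence.
#'
#' @param recording an [eeg_recording()] (typically causally filtered).
#' @param window_s window length in seconds (default 2).
#' @param step_s step between window starts in seconds (default 0.1).
#' @param t_start,t_end optional span (seconds) to window over; defaults to
#'   the whole stream.
#' @return an [epoch_set()] with `meta$t0` holding each window's start time.
#' @export
sliding_windows <- function(recording, window_s = 2, step_s = 0.1,
                            t_start = 0, t_end = recording_duration(recording)) {
  fs <- recording$sampling_rate
  win <- round(window_s * fs)
  step <- round(step_s * fs)
  s_first <- floor(t_start * fs) + 1L
  s_last <- floor(t_end * fs)
  avail <- s_last - s_first + 1L
  n_win <- if (avail < win) 0L else (avail - win) %/% step + 1L
  dat <- array(0, dim = c(nrow(recording$signal), win, n_win))
  t0 <- numeric(n_win)
  for (i in seq_len(n_win)) {
    s0 <- s_first + (i - 1L) * step
    dat[, , i] <- recording$signal[, s0:(s0 + win - 1)]
    t0[i] <- (s0 - 1) / fs
  }
  epoch_set(dat, rep(NA_character_, n_win), fs, recording$channel_names,
            data.frame(trial_id = rep(NA_integer_, n_win),
                       kind = rep("window", n_win),
                       t0 = t0, offset_s = rep(0, n_win)))
}

#' Downsample epochs with anti-aliasing
#'
#' Decimates each epoch by an integer factor after a zero-phase Butterworth
#' low-pass at 80% of the target Nyquist frequency. 2000-sample epochs at
#' 1000 Hz become 500-sample epochs at 250 Hz. Decimation preserves DC
#' exactly (the low-pass has unit gain at 0 Hz), and a target equal to the
#' original rate is the identity.
#'
#' @param epochs an [epoch_set()].
#' @param target_rate target sampling rate in Hz; the original rate must be
#'   an integer multiple.
#' @param lp_order anti-aliasing filter order (default 4).
#' @return the decimated [epoch_set()].
#' @export
downsample_epochs <- function(epochs, target_rate, lp_order = 4) {
  fs <- epochs$sampling_rate
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("original rate ", fs, " Hz is not an integer multiple of ",
         target_rate, " Hz")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(epochs)
  bt <- signal::butter(lp_order, 0.8 / factor, type = "low")
  d <- dim(epochs$data)
  idx <- seq(1, d[2], by = factor)
  out <- array(0, dim = c(d[1], length(idx), d[3]))
  for (i in seq_len(d[3])) {
    for (c_i in seq_len(d[1])) {
      out[c_i, , i] <- zero_phase(bt$b, bt$a, epochs$data[c_i, , i])[idx]
    }
  }
  epoch_set(out, epochs$labels, target_rate, epochs$channel_names, epochs$meta)
}
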