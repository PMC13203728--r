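#' Multi-channel EEG recording
#'
#' The common container passed between the simulator, the preprocessing chain
#' and the decoders: a channels x samples signal matrix in volts, a sampling
#' rate, ordered channel names, and an event table with one row per trigger.
#'
#' @param signal numeric matrix, channels x samples, amplitudes in volts.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_names character vector, one name per signal row.
#' @param events data.frame with at least columns `onset` (seconds from
#'   recording start), `code` (integer event code), `class` (class label) and
#'   `kind` (trial kind, e.g. `"AO+MI"`, `"MI"`, `"online"`). May be empty.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_names,
                          events = empty_events()) {
  signal <- as.matrix(signal)
  if (nrow(signal) != length(channel_names)) {
    stop("signal has ", nrow(signal), " rows but ", length(channel_names),
         " channel names were given")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  events <- as.data.frame(events)
  dur <- ncol(signal) / sampling_rate
  if (nrow(events) > 0 && (any(events$onset < 0) || any(events$onset > dur))) {
    stop("event onsets must lie within [0, ", signif(dur, 6), "] s")
  }
  rownames(signal) <- channel_names
  structure(
    list(signal = signal, sampling_rate = sampling_rate,
         channel_names = channel_names, events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              ncol(x$signal) / x$sampling_rate, nrow(x$events)))
  invisible(x)
}

empty_events <- function() {
  data.frame(onset = numeric(0), code = integer(0),
             class = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Duration of a recording in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$signal) / recording$sampling_rate
}
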