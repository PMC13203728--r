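#' Butterworth filter specification
#'
#' Thin wrapper over [signal::butter()] keeping the design parameters
#' alongside the coefficients.
#'
#' @param kind `"pass"` or `"stop"`.
#' @param band two-element band edges in Hz, `0 < low < high < fs/2`.
#' @param order filter order (>= 1).
#' @param sampling_rate sampling rate in Hz.
#' @param mode `"zero-phase"` (forward-backward, offline) or `"causal"`
#'   (streaming).
#' @return an object of class `filter_spec` with elements `b`, `a`.
#' @export
filter_spec <- function(kind = c("pass", "stop"), band, order, sampling_rate,
                        mode = c("zero-phase", "causal")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  stopifnot(order >= 1, length(band) == 2)
  if (!(0 < band[1] && band[1] < band[2] && band[2] < sampling_rate / 2)) {
    stop("band edges must satisfy 0 < low < high < sampling_rate/2 ",
         "(got ", band[1], "-", band[2], " Hz at ", sampling_rate, " Hz)")
  }
  bt <- signal::butter(order, band / (sampling_rate / 2), type = kind)
  structure(list(kind = kind, band = band, order = order,
                 sampling_rate = sampling_rate, mode = mode,
                 b = bt$b, a = bt$a),
            class = "filter_spec")
}

# steady-state direct-form-II-transposed state for a unit step input, so a
# filter started on a constant produces that constant times its DC gain
# from the first sample
lfilter_zi <- function(b, a) {
  b <- b / a[1]
  a <- a / a[1]
  n <- max(length(a), length(b))
  if (n == 1) return(numeric(0))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  companion <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2),
                                    rep(0, n - 2)))
  solve(diag(n - 1) - t(companion), b[2:n] - a[2:n] * b[1])
}

# zero-phase (forward-backward) filtering with odd-reflection padding and
# steady-state initial conditions at both passes, so constants and slow
# trends survive the filter edges exactly
zero_phase <- function(b, a, x) {
  n <- length(x)
  pad <- min(3 * (max(length(b), length(a)) - 1), n - 1)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  y <- df2t_filter(b, a, matrix(ext, 1), matrix(zi * ext[1], 1))$y[1, ]
  y <- rev(y)
  y <- df2t_filter(b, a, matrix(y, 1), matrix(zi * y[1], 1))$y[1, ]
  rev(y)[(pad + 1):(pad + n)]
}

apply_zero_phase <- function(spec, x) {
  # x: channels x samples
  t(apply(x, 1, function(ch) zero_phase(spec$b, spec$a, ch)))
}

#' Offline preprocessing filter chain
#'
#' Applies, in this order: a 1-100 Hz band-pass, a 60 Hz band-stop
#' (58-62 Hz), a hard amplitude clamp at +/-50 uV, and a final 4-40 Hz
#' band-pass. All filters are zero-phase (forward-backward) Butterworth
#' designs: band-passes of order `bp_order`, notch of order `notch_order`.
#' Clipping is saturation, not trial rejection.
#'
#' @param recording an [eeg_recording()] with sampling rate of at least
#'   250 Hz (the 100 Hz edge must lie below Nyquist).
#' @param clip_uV clamp magnitude in microvolts (default 50).
#' @param bp_order,notch_order Butterworth orders (defaults 4 and 2).
#' @return the filtered [eeg_recording()].
#' @export
offline_filter_chain <- function(recording, clip_uV = 50,
                                 bp_order = 4, notch_order = 2) {
  fs <- recording$sampling_rate
  if (fs < 250) {
    stop("sampling rate must be at least 250 Hz for the 1-100 Hz band-pass ",
         "(got ", fs, " Hz)")
  }
  bp1 <- filter_spec("pass", c(1, 100), bp_order, fs)
  notch <- filter_spec("stop", c(58, 62), notch_order, fs)
  bp2 <- filter_spec("pass", c(4, 40), bp_order, fs)
  x <- recording$signal
  x <- apply_zero_phase(bp1, x)
  x <- apply_zero_phase(notch, x)
  clip <- clip_uV * 1e-6
  x[x > clip] <- clip
  x[x < -clip] <- -clip
  x <- apply_zero_phase(bp2, x)
  out <- eeg_recording(x, fs, recording$channel_names, recording$events)
  # pipeline trace: the stage order is part of the preprocessing contract
  attr(out, "stages") <- c("bandpass_1_100", "bandstop_58_62",
                           sprintf("clip_%guV", clip_uV), "bandpass_4_40")
  out
}

#' Stateful causal filter for streaming decode
#'
#' `online_filter_state()` creates the causal third-order Butterworth
#' 8-30 Hz band-pass used on the real-time path; `online_filter_chunk()`
#' filters one chunk and carries the filter state, so chunked filtering is
#' bit-identical to filtering the whole stream at once; `online_filter()`
#' filters a whole recording causally in one call.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param band band edges in Hz (default 8-30).
#' @param order filter order (default 3).
#' @param n_channels number of channels the state tracks.
#' @return `online_filter_state()`: an `online_filter_state` object;
#'   `online_filter_chunk()`: `list(y, state)`; `online_filter()`: a filtered
#'   [eeg_recording()].
#' @export
online_filter_state <- function(sampling_rate, band = c(8, 30), order = 3,
                                n_channels = 8) {
  spec <- filter_spec("pass", band, order, sampling_rate, mode = "causal")
  n <- max(length(spec$b), length(spec$a))
  structure(list(spec = spec,
                 zi = matrix(0, n_channels, n - 1)),
            class = "online_filter_state")
}

#' @rdname online_filter_state
#' @param state an `online_filter_state`.
#' @param x channels x samples chunk matrix.
#' @export
online_filter_chunk <- function(state, x) {
  stopifnot(inherits(state, "online_filter_state"))
  x <- as.matrix(x)
  if (nrow(x) != nrow(state$zi)) {
    stop("chunk has ", nrow(x), " channels; state expects ", nrow(state$zi))
  }
  out <- df2t_filter(state$spec$b, state$spec$a, x, state$zi)
  state$zi <- out$zf
  list(y = out$y, state = state)
}

#' Causally decimate a stream to a lower rate
#'
#' Streaming-safe decimation: a causal Butterworth low-pass at 80% of the
#' target Nyquist frequency followed by sample picking. Event times are in
#' seconds and remain valid. Used on the real-time path so sliding windows
#' arrive directly at the decoder's epoch rate.
#'
#' @param recording an [eeg_recording()].
#' @param target_rate target rate in Hz; the original must be an integer
#'   multiple.
#' @param lp_order anti-aliasing filter order (default 4).
#' @return the decimated [eeg_recording()].
#' @export
downsample_recording <- function(recording, target_rate, lp_order = 4) {
  fs <- recording$sampling_rate
  factor <- fs / target_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop("original rate ", fs, " Hz is not an integer multiple of ",
         target_rate, " Hz")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(recording)
  bt <- signal::butter(lp_order, 0.8 / factor, type = "low")
  n <- max(length(bt$b), length(bt$a))
  out <- df2t_filter(bt$b, bt$a, recording$signal,
                     matrix(0, nrow(recording$signal), n - 1))
  eeg_recording(out$y[, seq(1, ncol(out$y), by = factor), drop = FALSE],
                target_rate, recording$channel_names, recording$events)
}

#' @rdname online_filter_state
#' @param recording an [eeg_recording()].
#' @export
online_filter <- function(recording, band = c(8, 30), order = 3) {
  st <- online_filter_state(recording$sampling_rate, band, order,
                            n_channels = nrow(recording$signal))
  res <- online_filter_chunk(st, recording$signal)
  eeg_recording(res$y, recording$sampling_rate, recording$channel_names,
                recording$events)
}
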