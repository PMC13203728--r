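# 1/f-shaped Gaussian noise, one column per channel is generated separately;
# DC bin is zeroed so the background is mean-free by construction.
pink_noise <- function(n, exponent, fs) {
  w <- rnorm(n)
  spec <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n          # two-sided frequency axis
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  x / sd(x)
}

# raised-cosine attenuation profile over [on, off] sample indices
attenuation_profile <- function(n, on, off, depth, ramp) {
  w <- numeric(n)
  if (off < on) return(w)
  len <- off - on + 1
  r <- min(ramp, floor(len / 2))
  core <- rep(1, len)
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    core[seq_len(r)] <- up
    core[len - r + seq_len(r)] <- rev(up)
  }
  w[on:off] <- core * depth
  w
}

#' Synthesize a multi-channel EEG recording from a protocol plan
#'
#' Generates `1/f`-shaped background noise on every channel and adds an
#' alpha-band rhythm (narrowband-filtered noise) to the sensorimotor
#' channels. During each trial's imagery window the rhythm amplitude at the
#' channels named by `config$erd_map[[class]]` is attenuated by the
#' configured fraction, with short raised-cosine ramps at the window edges;
#' everywhere else the rhythm stays at baseline amplitude. The imagery window
#' is the 3 s movement period for offline trials and the cue-plus-
#' classification span for online attempts.
#'
#' The rhythm amplitude is calibrated per channel against the realized
#' in-band background power so that `config$snr` is the in-band
#' rhythm-to-background power ratio; see [sim_config()] for the resulting
#' closed-form ERD expectation.
#'
#' The returned recording carries its additive components (background and
#' modulated rhythm) as an attribute so [apply_session_drift()] can rescale
#' the rhythm-to-noise ratio exactly.
#'
#' @param config a [sim_config()].
#' @param plan a `protocol_plan` from [build_offline_protocol()] or
#'   [build_online_protocol()].
#' @param tail_s trailing silence appended after the last trial (seconds).
#' @return an [eeg_recording()] whose event table mirrors the plan (one row
#'   per plan row: per trial offline, per attempt online).
#' @export
synthesize_recording <- function(config, plan, tail_s = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(plan) || nrow(plan) == 0) stop("plan must be non-empty")
  missing_cls <- setdiff(unique(plan$class), names(config$erd_map))
  if (length(missing_cls) > 0) {
    stop("configuration error: plan classes missing from erd_map: ",
         paste(missing_cls, collapse = ", "))
  }
  fs <- config$sampling_rate
  n_ch <- length(config$channel_names)
  n <- ceiling((max(plan$t_end) + tail_s) * fs)

  with_seed(config$seed, {
    bg <- matrix(0, n_ch, n)
    for (c_i in seq_len(n_ch)) {
      bg[c_i, ] <- pink_noise(n, config$background_exponent, fs) *
        config$background_rms
    }

    bf <- signal::butter(4, config$alpha_band / (fs / 2), type = "pass")
    rhythm <- matrix(0, n_ch, n)
    if (config$snr > 0) {
      for (ch in config$rhythm_channels) {
        c_i <- match(ch, config$channel_names)
        raw <- zero_phase(bf$b, bf$a, rnorm(n))
        inband_bg <- var(zero_phase(bf$b, bf$a, bg[c_i, ]))
        rhythm[c_i, ] <- raw / sd(raw) * sqrt(config$snr * inband_bg)
      }
    }

    # amplitude modulation: 1 - a inside each imagery window
    ramp <- round(0.15 * fs)
    online <- identical(attr(plan, "protocol"), "online") ||
      ("attempt" %in% names(plan))
    env <- matrix(1, n_ch, n)
    for (i in seq_len(nrow(plan))) {
      cls <- plan$class[i]
      amap <- config$erd_map[[cls]]
      win_s <- if (online) plan$cue_s[i] + plan$window_s[i] else plan$move_s[i]
      on <- floor(plan$onset[i] * fs) + 1
      off <- min(n, floor((plan$onset[i] + win_s) * fs))
      for (ch in names(amap)) {
        a <- amap[[ch]]
        if (a <= 0) next
        c_i <- match(ch, config$channel_names)
        env[c_i, ] <- env[c_i, ] * (1 - attenuation_profile(n, on, off, a, ramp))
      }
    }

    mod_rhythm <- env * rhythm
    sig <- bg + mod_rhythm
    events <- data.frame(
      onset = plan$onset,
      code = match(plan$class, config$classes),
      class = plan$class,
      kind = plan$kind,
      trial_id = plan$trial_id,
      stringsAsFactors = FALSE)
    if ("attempt" %in% names(plan)) events$attempt <- plan$attempt
    rec <- eeg_recording(sig, fs, config$channel_names, events)
    attr(rec, "components") <- list(background = bg, rhythm = mod_rhythm)
    rec
  })
}

#' Apply session-to-session drift to a recording
#'
#' Emulates dry-electrode non-stationarity: each channel is scaled by a
#' multiplicative gain and shifted by an additive baseline offset, and the
#' rhythm-to-background power ratio is rescaled by `drift$snr_scale`
#' (requires the component decomposition attached by
#' [synthesize_recording()]). Events are unchanged. Gains/offsets not given
#' explicitly are drawn per channel under `seed` (gain ~ N(1, gain_sd)
#' truncated positive, offset ~ N(0, offset_sd)).
#'
#' @param recording an [eeg_recording()].
#' @param drift a [drift_spec()].
#' @param seed integer seed for random gain/offset draws.
#' @return the drifted [eeg_recording()], with the realized drift attached as
#'   attribute `"drift"` and updated components for further drifting.
#' @export
apply_session_drift <- function(recording, drift, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(drift, "drift_spec"))
  n_ch <- nrow(recording$signal)
  with_seed(seed, {
    gain <- drift$gain
    if (is.null(gain)) gain <- pmax(rnorm(n_ch, 1, drift$gain_sd), 0.05)
    offset <- drift$offset
    if (is.null(offset)) offset <- rnorm(n_ch, 0, drift$offset_sd)
    if (any(gain <= 0)) stop("drift gains must be positive")

    comp <- attr(recording, "components")
    if (is.null(comp)) {
      if (drift$snr_scale != 1) {
        stop("snr_scale != 1 requires the component decomposition attached ",
             "by synthesize_recording()")
      }
      sig <- recording$signal * gain + offset
      out <- eeg_recording(sig, recording$sampling_rate,
                           recording$channel_names, recording$events)
    } else {
      bg <- comp$background * gain + offset
      rh <- comp$rhythm * gain * sqrt(drift$snr_scale)
      out <- eeg_recording(bg + rh, recording$sampling_rate,
                           recording$channel_names, recording$events)
      attr(out, "components") <- list(background = bg, rhythm = rh)
    }
    attr(out, "drift") <- list(gain = gain, offset = offset,
                               snr_scale = drift$snr_scale)
    out
  })
}
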