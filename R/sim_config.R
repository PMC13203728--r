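#' Configuration of the synthetic sensorimotor-rhythm EEG generator
#'
#' Defines the statistical structure of simulated sessions: an eight-channel
#' 10-20 montage, 1/f background noise, alpha-band rhythms over the
#' sensorimotor channels, and a class-to-channel map of event-related
#' desynchronization (ERD) depths. The defaults encode the standard
#' contralateral organization of hand imagery (left hand attenuates the
#' right-hemisphere rhythm at C4, right hand attenuates C3) and midline
#' organization of foot imagery (Cz).
#'
#' `snr` is the ratio of rhythm power to background power *within the alpha
#' band* at each rhythm-carrying channel; the generator calibrates the rhythm
#' amplitude against the realized background so that the expected measured
#' ERD for an injected attenuation `a` has the closed form
#' `-(1 - (1 - a)^2) * snr / (1 + snr) * 100` percent.
#'
#' @param sampling_rate sampling rate in Hz (default 1000).
#' @param channel_names ordered montage labels (default the 8-channel
#'   sensorimotor montage F3, F4, C3, Cz, C4, P3, Pz, P4).
#' @param classes class set; the last level is the rest/idle class.
#' @param erd_map named list, class -> named numeric vector of fractional
#'   alpha-amplitude attenuations in `[0, 1]` per channel. Attenuation 0
#'   means no ERD at that channel.
#' @param alpha_band rhythm band in Hz (default 8-14).
#' @param background_exponent spectral slope of the 1/f background (power
#'   ~ 1/f^exponent; default 1, i.e. pink noise).
#' @param background_rms background standard deviation per channel in volts
#'   (default 10 microvolts, typical of dry-electrode scalp EEG after
#'   amplifier scaling; keeps ordinary samples well inside the +/-50 uV
#'   artifact clamp).
#' @param snr in-band rhythm-to-background power ratio (default 1).
#' @param rhythm_channels channels carrying an alpha rhythm (default C3, Cz,
#'   C4). Every channel referenced by `erd_map` must carry a rhythm.
#' @param seed integer seed; identical (config, plan) pairs reproduce
#'   identical recordings bit for bit.
#' @return an object of class `sim_config`.
#' @seealso [synthesize_recording()], [build_offline_protocol()]
#' @export
sim_config <- function(sampling_rate = 1000,
                       channel_names = SMR_CHANNELS,
                       classes = SMR_CLASSES,
                       erd_map = default_erd_map(),
                       alpha_band = c(8, 14),
                       background_exponent = 1,
                       background_rms = 10e-6,
                       snr = 1,
                       rhythm_channels = c("C3", "Cz", "C4"),
                       seed = 1L) {
  stopifnot(sampling_rate > 0, length(alpha_band) == 2,
            alpha_band[1] < alpha_band[2], snr >= 0, background_rms > 0)
  for (cls in names(erd_map)) {
    a <- erd_map[[cls]]
    if (any(a < 0 | a > 1)) {
      stop("erd_map attenuations must lie in [0, 1] (class ", cls, ")")
    }
    if (!all(names(a) %in% channel_names)) {
      stop("erd_map for class ", cls, " references unknown channels")
    }
    if (!all(names(a)[a > 0] %in% rhythm_channels)) {
      stop("erd_map for class ", cls,
           " attenuates a channel that carries no rhythm")
    }
  }
  if (!all(rhythm_channels %in% channel_names)) {
    stop("rhythm_channels must be a subset of channel_names")
  }
  structure(
    list(sampling_rate = sampling_rate, channel_names = channel_names,
         classes = classes, erd_map = erd_map, alpha_band = alpha_band,
         background_exponent = background_exponent,
         background_rms = background_rms, snr = snr,
         rhythm_channels = rhythm_channels, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default class-to-channel ERD map
#'
#' Contralateral hand / midline foot organization: left-hand imagery
#' attenuates C4, right-hand imagery C3, both-feet imagery Cz. Real
#' topographies are subject-variable; the map is fully configurable.
#'
#' @param depth fractional amplitude attenuation in `[0, 1]` (default 0.4).
#' @return named list usable as the `erd_map` argument of [sim_config()].
#' @export
default_erd_map <- function(depth = 0.4) {
  list(left_hand = c(C4 = depth),
       right_hand = c(C3 = depth),
       both_feet = c(Cz = depth))
}

#' Session drift specification
#'
#' A linear-Gaussian model of dry-electrode non-stationarity: per-channel
#' multiplicative gains, additive baseline offsets, and a rescaling of the
#' rhythm-to-background power ratio. Gains model contact-impedance changes,
#' offsets model baseline wander, and the SNR scale models fatigue or
#' electrode-seating loss of rhythm salience.
#'
#' Either supply explicit per-channel `gain` / `offset` vectors, or standard
#' deviations from which [apply_session_drift()] draws them (gain ~ N(1,
#' `gain_sd`), offset ~ N(0, `offset_sd`)).
#'
#' @param gain_sd standard deviation of random per-channel gains (default 0.1).
#' @param offset_sd standard deviation of random offsets in volts (default 0).
#' @param snr_scale multiplicative factor on rhythm power (default 1).
#' @param gain,offset optional explicit per-channel vectors overriding the
#'   random draw.
#' @return an object of class `drift_spec`.
#' @export
drift_spec <- function(gain_sd = 0.1, offset_sd = 0, snr_scale = 1,
                       gain = NULL, offset = NULL) {
  stopifnot(gain_sd >= 0, offset_sd >= 0, snr_scale >= 0)
  if (!is.null(gain) && any(gain <= 0)) stop("drift gains must be positive")
  structure(list(gain_sd = gain_sd, offset_sd = offset_sd,
                 snr_scale = snr_scale, gain = gain, offset = offset),
            class = "drift_spec")
}
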