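#' Time-resolved band power of epochs
#'
#' Band-pass filters each epoch channel in the target band (zero-phase
#' 4th-order Butterworth) and squares the amplitude, giving a per-sample
#' power estimate.
#'
#' @param epochs an [epoch_set()].
#' @param band frequency band in Hz (default the 8-14 Hz alpha band).
#' @param order Butterworth order (default 4).
#' @return an [epoch_set()]-shaped object whose data holds nonnegative
#'   power values (class `band_power_series`).
#' @export
band_power <- function(epochs, band = c(8, 14), order = 4) {
  fs <- epochs$sampling_rate
  if (band[2] >= fs / 2) {
    stop("band edge ", band[2], " Hz is at or above Nyquist (", fs / 2, " Hz)")
  }
  bt <- signal::butter(order, band / (fs / 2), type = "pass")
  d <- dim(epochs$data)
  out <- epochs
  for (i in seq_len(d[3])) {
    for (c_i in seq_len(d[1])) {
      out$data[c_i, , i] <- zero_phase(bt$b, bt$a, epochs$data[c_i, , i])^2
    }
  }
  class(out) <- c("band_power_series", class(out))
  out
}

# time-average power per (channel, trial), optionally trimming filter-edge
# transients from both ends of each epoch
trial_power <- function(series, edge_trim_s = 0.25) {
  d <- dim(series$data)
  trim <- round(edge_trim_s * series$sampling_rate)
  keep <- (trim + 1):(d[2] - trim)
  if (length(keep) < 1) stop("edge trim leaves no samples")
  apply(series$data[, keep, , drop = FALSE], c(1, 3), mean)  # channels x trials
}

#' Mean band power of one class
#'
#' Averages the per-trial band power (time mean over the analysis window,
#' with `edge_trim_s` excluded at both ends to suppress filter ringing) over
#' all trials of the class.
#'
#' @param series a [band_power()] result.
#' @param class class label to average.
#' @param edge_trim_s seconds trimmed from each end (default 0.25).
#' @return named per-channel vector of mean power.
#' @export
class_mean_power <- function(series, class, edge_trim_s = 0.25) {
  idx <- which(series$labels == class)
  if (length(idx) == 0) stop("no trials with class ", class)
  tp <- trial_power(series, edge_trim_s)
  out <- rowMeans(tp[, idx, drop = FALSE])
  names(out) <- series$channel_names
  out
}

#' Rest baseline power
#'
#' Grand mean over all time samples of all rest trials (equal-length trials
#' make this the mean of per-trial means), one scalar per channel.
#'
#' @param series a [band_power()] result holding the rest/baseline epochs.
#' @param edge_trim_s seconds trimmed from each end (default 0.25).
#' @return named per-channel vector of baseline power.
#' @export
rest_baseline <- function(series, edge_trim_s = 0.25) {
  if (n_epochs(series) == 0) stop("rest set is empty")
  tp <- trial_power(series, edge_trim_s)
  out <- rowMeans(tp)
  names(out) <- series$channel_names
  out
}

#' ERD/ERS percentage
#'
#' Relative band-power change of a class against the rest baseline:
#' `(P_class - P_rest) / P_rest * 100`. Negative values (ERD) indicate
#' power attenuation, i.e. cortical activation during imagery; positive
#' values (ERS) indicate synchronization. The statistic is a power ratio,
#' so it is invariant to any common amplitude scaling.
#'
#' @param p_class class mean power (scalar or per-channel vector).
#' @param p_rest baseline power (same shape, strictly positive).
#' @return ERD/ERS in percent.
#' @export
erd_percent <- function(p_class, p_rest) {
  if (any(p_rest <= 0)) stop("baseline power must be positive")
  (p_class - p_rest) / p_rest * 100
}

#' Analysis and baseline windows per condition
#'
#' Offline trials use the 3 s interval after cue onset as the imagery
#' window; online trials use the 2.5 s interval before the model-triggered
#' movement. Both use the 2 s pre-cue interval as the resting baseline.
#'
#' @param condition `"offline"` or `"online"`.
#' @return list with `mi` and `baseline`, each `c(start, end)` in seconds
#'   relative to the window's anchor (cue onset for `mi` offline and for
#'   `baseline` always; motion onset for `mi` online).
#' @export
erd_windows <- function(condition) {
  switch(condition,
         offline = list(mi = c(0, 3), baseline = c(-2, 0)),
         online = list(mi = c(-2.5, 0), baseline = c(-2, 0)),
         stop("unknown condition: ", condition,
              " (expected \"offline\" or \"online\")"))
}

#' Class x channel ERD/ERS table for a recording
#'
#' Extracts imagery and baseline windows per [erd_windows()], computes alpha
#' band power, and tabulates the ERD/ERS percentage per class and channel.
#' For the online condition, `mi_events$onset` must hold the confirmed
#' motion onsets of successfully triggered trials (with their `class`), and
#' `baseline_events$onset` the cue onsets.
#'
#' @param recording an [eeg_recording()] (raw or lightly filtered; the band
#'   filter isolates the rhythm regardless).
#' @param condition `"offline"` or `"online"`.
#' @param channels channels to analyze; the standard sensorimotor set is
#'   C3, Cz, C4 and other choices are flagged with a warning.
#' @param band analysis band in Hz (default 8-14).
#' @param classes movement classes to tabulate.
#' @param mi_events,baseline_events event tables overriding the recording's
#'   own (required for `condition = "online"`).
#' @param edge_trim_s filter-transient trim (default 0.25 s).
#' @return an `erd_result`: list with `table` (class x channel percentages),
#'   `p_class`, `p_rest`, and trial counts `n_class`, `n_rest`.
#' @export
erd_analysis <- function(recording, condition = c("offline", "online"),
                         channels = c("C3", "Cz", "C4"), band = c(8, 14),
                         classes = SMR_MOVEMENT_CLASSES,
                         mi_events = NULL, baseline_events = NULL,
                         edge_trim_s = 0.25) {
  condition <- match.arg(condition)
  if (!all(channels %in% c("C3", "Cz", "C4"))) {
    warning("non-standard channel selection for ERD analysis: ",
            paste(setdiff(channels, c("C3", "Cz", "C4")), collapse = ", "))
  }
  win <- erd_windows(condition)
  if (is.null(mi_events)) {
    if (condition == "online") {
      stop("online ERD analysis needs mi_events with motion onsets")
    }
    mi_events <- recording$events
  }
  if (is.null(baseline_events)) {
    if (condition == "online") {
      stop("online ERD analysis needs baseline_events with cue onsets")
    }
    baseline_events <- recording$events
  }
  mi_events <- mi_events[mi_events$class %in% classes, , drop = FALSE]

  mi_ep <- extract_epochs(recording, diff(win$mi), win$mi[1],
                          events = mi_events)
  rest_ep <- extract_epochs(recording, diff(win$baseline), win$baseline[1],
                            events = baseline_events, label = "rest")
  mi_pow <- band_power(mi_ep, band)
  rest_pow <- band_power(rest_ep, band)
  p_rest <- rest_baseline(rest_pow, edge_trim_s)

  ch_idx <- match(channels, recording$channel_names)
  if (anyNA(ch_idx)) stop("unknown channel(s) requested")
  tab <- matrix(NA_real_, length(classes), length(channels),
                dimnames = list(classes, channels))
  p_class <- tab
  n_class <- integer(length(classes))
  for (k in seq_along(classes)) {
    pc <- class_mean_power(mi_pow, classes[k], edge_trim_s)
    p_class[k, ] <- pc[ch_idx]
    tab[k, ] <- erd_percent(pc[ch_idx], p_rest[ch_idx])
    n_class[k] <- sum(mi_pow$labels == classes[k])
  }
  structure(list(table = tab, p_class = p_class, p_rest = p_rest[ch_idx],
                 n_class = stats::setNames(n_class, classes),
                 n_rest = n_epochs(rest_pow), condition = condition,
                 band = band),
            class = "erd_result")
}

#' @export
print.erd_result <- function(x, ...) {
  cat(sprintf("<erd_result> %s condition, %g-%g Hz, %d rest trials\n",
              x$condition, x$band[1], x$band[2], x$n_rest))
  print(round(x$table, 1))
  invisible(x)
}

#' Paired nonparametric comparison of two conditions
#'
#' Two-sided paired Wilcoxon signed-rank test. Zero differences are
#' dropped, following the signed-rank convention; if every pair is tied
#' the statistic is 0 and p = 1 (no evidence of a difference). For
#' tie-free data the exact small-sample distribution of
#' [stats::wilcox.test()] is used; when tied absolute differences would
#' force that implementation onto its normal approximation, samples of up
#' to 14 effective pairs instead get an exact p-value by enumerating all
#' 2^n sign assignments of the (mid-)ranked differences.
#'
#' @param a,b paired per-subject (or per-trial) values, equal length >= 2.
#' @return list with `statistic` (V), `p_value`, and `n_effective`
#'   (non-zero pairs).
#' @export
compare_conditions <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired (equal length)")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n_effective = 0L))
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (has_ties && n <= 14) {
    v_all <- as.matrix(expand.grid(rep(list(c(0, 1)), n))) %*% r
    p <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d))
    p <- wt$p.value
  }
  list(statistic = unname(v_obs), p_value = p, n_effective = n)
}
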