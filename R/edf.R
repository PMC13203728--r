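# Minimal European Data Format (EDF) support for continuous multi-channel
# recordings with a uniform sampling rate. Signals are quantized to 16-bit
# integers against per-channel symmetric physical ranges; the original
# sample count is noted in the reserved header field so zero-padding of the
# final data record can be trimmed on read. Events live out-of-band in a
# sibling tab-separated file (EDF annotation dialects vary too much to be a
# reliable interchange).

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

events_path_for <- function(path) sub("\\.edf$", ".events.tsv", path)

#' Write a recording as EDF plus an events TSV
#'
#' @param recording an [eeg_recording()].
#' @param path output file path (conventionally `.edf`); the event table is
#'   written next to it as `<name>.events.tsv`.
#' @return the EDF path, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  sig <- recording$signal
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  n_ch <- nrow(sig)
  n <- ncol(sig)
  n_rec <- ceiling(n / fs)

  # symmetric physical range per channel, in microvolts for readability
  phys_max <- apply(abs(sig), 1, max) * 1e6
  phys_max[phys_max == 0] <- 1
  phys_max <- signif(phys_max * 1.0001, 7)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + n_ch), 8),
    pad_field(sprintf("SMRBCI n=%d", n), 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(n_ch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(recording$channel_names, function(ch) pad_field(paste("EEG", ch), 16), ""),
    rep(pad_field("dry electrode", 80), n_ch),
    rep(pad_field("uV", 8), n_ch),
    vapply(-phys_max, pad_field, "", width = 8),
    vapply(phys_max, pad_field, "", width = 8),
    rep(pad_field("-32768", 8), n_ch),
    rep(pad_field("32767", 8), n_ch),
    rep(pad_field("", 80), n_ch),
    rep(pad_field(fs, 8), n_ch),
    rep(pad_field("", 32), n_ch))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)

  gain <- phys_max / 32767          # uV per digital unit
  padded <- matrix(0, n_ch, n_rec * fs)
  padded[, seq_len(n)] <- sig * 1e6
  dig <- round(padded / gain)
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  write_events(recording$events, events_path_for(path))
  invisible(path)
}

#' Read an EDF recording and its sibling events TSV
#'
#' @param path path to the `.edf` file; events are read from
#'   `<name>.events.tsv`, which must exist.
#' @param channels optional channel subset/order to return (montage
#'   reordering honors this order).
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, channels = NULL) {
  ev_path <- events_path_for(path)
  if (!file.exists(ev_path)) {
    stop("missing events file: ", ev_path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  read_chars <- function(nc, what, offset) {
    raw <- readChar(con, nc, useBytes = TRUE)
    if (nchar(raw, type = "bytes") < nc) {
      stop("truncated EDF header: expected ", what, " at byte offset ", offset)
    }
    raw
  }
  read_chars(8, "version", 0)
  read_chars(160, "patient/recording ids", 8)
  read_chars(16, "start date/time", 168)
  read_chars(8, "header length", 184)
  reserved <- read_chars(44, "reserved", 192)
  n_rec <- as.integer(read_chars(8, "record count", 236))
  rec_dur <- as.numeric(read_chars(8, "record duration", 244))
  n_ch <- as.integer(read_chars(4, "signal count", 252))

  sig_field <- function(width, what, base) {
    vapply(seq_len(n_ch), function(i) {
      trimws(read_chars(width, what, base + (i - 1) * width))
    }, "")
  }
  base <- 256
  labels <- sig_field(16, "labels", base); base <- base + 16 * n_ch
  sig_field(80, "transducers", base); base <- base + 80 * n_ch
  sig_field(8, "dimensions", base); base <- base + 8 * n_ch
  pmin_ <- as.numeric(sig_field(8, "physical minima", base)); base <- base + 8 * n_ch
  pmax_ <- as.numeric(sig_field(8, "physical maxima", base)); base <- base + 8 * n_ch
  dmin_ <- as.numeric(sig_field(8, "digital minima", base)); base <- base + 8 * n_ch
  dmax_ <- as.numeric(sig_field(8, "digital maxima", base)); base <- base + 8 * n_ch
  sig_field(80, "prefiltering", base); base <- base + 80 * n_ch
  spr <- as.integer(sig_field(8, "samples per record", base)); base <- base + 8 * n_ch
  sig_field(32, "signal reserved", base)

  if (length(unique(spr)) != 1) stop("mixed per-signal rates are not supported")
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  sig <- matrix(0, n_ch, total)
  for (r in seq_len(n_rec)) {
    for (c_i in seq_len(n_ch)) {
      vals <- readBin(con, integer(), n = spr[1], size = 2, endian = "little")
      if (length(vals) < spr[1]) {
        offset <- 256 * (1 + n_ch) +
          2 * ((r - 1) * sum(spr) + (c_i - 1) * spr[1] + length(vals))
        stop("truncated EDF data: record ", r, ", signal ", c_i,
             " at byte offset ", offset)
      }
      sig[c_i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- vals
    }
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  sig <- sig * gain * 1e-6          # back to volts
  m <- regmatches(reserved, regexec("n=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) sig <- sig[, seq_len(as.integer(m[2])), drop = FALSE]
  ch_names <- sub("^EEG ", "", labels)
  events <- read_events(ev_path)
  rec <- eeg_recording(sig, fs, ch_names, events)
  if (!is.null(channels)) {
    idx <- match(channels, ch_names)
    if (anyNA(idx)) {
      stop("channel-count/name mismatch: requested ",
           paste(channels[is.na(idx)], collapse = ", "))
    }
    rec <- eeg_recording(sig[idx, , drop = FALSE], fs, channels, events)
  }
  rec
}

#' Write / read an event table as tab-separated text
#'
#' Columns: `onset` (s), `code`, `class`, `kind`, plus any extra columns
#' (e.g. `trial_id`, `attempt`).
#'
#' @param events event data.frame.
#' @param path TSV path.
#' @return `read_events` returns the event data.frame.
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
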