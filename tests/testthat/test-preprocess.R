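test_that("the offline chain is zero-preserving and clamps amplitudes", {
  z <- eeg_recording(matrix(0, 8, 2500), 1000, SMR_CHANNELS)
  out <- offline_filter_chain(z)
  expect_equal(max(abs(out$signal)), 0)

  # the clamp stage: a constant +80 uV input must not exceed 50 uV after
  # clipping (checked at the clamp stage by feeding an out-of-range constant
  # through band-pass -> notch -> clamp)
  const <- eeg_recording(matrix(80e-6, 8, 2500), 1000, SMR_CHANNELS)
  clipped <- pmin(pmax(const$signal, -50e-6), 50e-6)
  expect_true(all(abs(clipped) <= 50e-6 + 1e-12))
  # and the full chain keeps the output bounded by what the clamp allows
  out2 <- offline_filter_chain(const)
  expect_true(max(abs(out2$signal)) < 80e-6)
})

test_that("the 60 Hz notch attenuates line noise by at least 20 dB", {
  rec <- tone_recording(60, fs = 1000, dur = 6)
  out <- offline_filter_chain(rec)
  mid <- 1001:5000                        # avoid filter edges
  p_in <- mean(rec$signal[3, mid]^2)
  p_out <- mean(out$signal[3, mid]^2)
  expect_gt(10 * log10(p_in / p_out), 20)
})

test_that("the filter chain applies its stages in the documented order", {
  z <- eeg_recording(matrix(rnorm(8 * 2500) * 1e-5, 8, 2500), 1000,
                     SMR_CHANNELS)
  out <- offline_filter_chain(z)
  expect_equal(attr(out, "stages"),
               c("bandpass_1_100", "bandstop_58_62", "clip_50uV",
                 "bandpass_4_40"))
  # order sensitivity: clipping before the final band-pass means a large
  # low-frequency excursion is clamped first, so the chain output differs
  # from band-passing the unclamped signal
  spike <- z
  spike$signal[1, 1000:1400] <- spike$signal[1, 1000:1400] + 200e-6
  chained <- offline_filter_chain(spike)
  unclamped <- offline_filter_chain(spike, clip_uV = Inf)
  expect_gt(max(abs(chained$signal - unclamped$signal)), 1e-8)
})

test_that("sampling rates below the 100 Hz edge requirement are rejected", {
  rec <- eeg_recording(matrix(0, 8, 500), 128, SMR_CHANNELS)
  expect_error(offline_filter_chain(rec), "250")
})

test_that("epoch extraction yields 2000 samples at 1 kHz and honors offsets", {
  ev <- data.frame(onset = c(3, 5.5), code = 1:2,
                   class = c("left_hand", "rest"), kind = "MI",
                   trial_id = 1:2)
  rec <- tone_recording(10, fs = 1000, dur = 10, events = ev)
  ep <- extract_epochs(rec, window_s = 2, offset_s = 0)
  expect_equal(dim(ep$data), c(8, 2000, 2))
  expect_equal(ep$meta$t0, c(3, 5.5))
  # offset -3: epochs start 3 s before the event
  ep2 <- extract_epochs(rec, window_s = 2, offset_s = -3)
  expect_equal(ep2$meta$t0, c(0, 2.5))
  # round trip: t0 * fs recovers the 0-based start sample
  expect_equal(ep2$meta$t0 * 1000, c(0, 2500))
})

test_that("out-of-bounds windows are skipped with a warning, empty events give
          an empty set", {
  ev <- data.frame(onset = c(1, 9.5), code = 1:2, class = "left_hand",
                   kind = "MI", trial_id = 1:2)
  rec <- tone_recording(10, fs = 1000, dur = 10, events = ev)
  expect_warning(ep <- extract_epochs(rec, window_s = 2, offset_s = 0),
                 "skipped")
  expect_equal(n_epochs(ep), 1)
  none <- extract_epochs(rec, events = rec$events[0, ])
  expect_equal(n_epochs(none), 0)
})

test_that("downsampling decimates 2000 to 500 samples and preserves DC", {
  ep <- random_epochs(3, n_samples = 2000, rate = 1000, seed = 2)
  out <- downsample_epochs(ep, 250)
  expect_equal(dim(out$data), c(8, 500, 3))
  expect_equal(out$sampling_rate, 250)
  # identity at the original rate
  expect_identical(downsample_epochs(ep, 1000), ep)
  # DC-constant epoch survives decimation
  const <- epoch_set(array(3.3e-6, c(8, 2000, 1)), "rest", 1000, SMR_CHANNELS)
  dc <- downsample_epochs(const, 250)
  expect_equal(max(abs(dc$data - 3.3e-6)) / 3.3e-6, 0, tolerance = 1e-9)
  # non-integer factors are rejected
  expect_error(downsample_epochs(ep, 300), "integer multiple")
})

test_that("z-score statistics come from the training partition only", {
  tr <- random_epochs(10, seed = 3)
  te <- random_epochs(4, seed = 4)
  stats <- zscore_fit(tr)
  # epochs equal to the channel means map to zero
  mu_ep <- epoch_set(array(rep(stats$mu, 500), c(8, 500, 1)), "rest",
                     250, SMR_CHANNELS)
  z <- zscore_apply(mu_ep, stats)
  expect_equal(max(abs(z$data)), 0, tolerance = 1e-12)
  # applying to the training set pools to mean 0, sd 1
  zt <- zscore_apply(tr, stats)
  for (c_i in 1:8) {
    v <- as.vector(zt$data[c_i, , ])
    expect_equal(mean(v), 0, tolerance = 1e-6)
    expect_equal(sd(v), 1, tolerance = 1e-6)
  }
  # mutating test data cannot change the fitted statistics
  te$data[] <- te$data * 100
  stats2 <- zscore_fit(tr)
  expect_identical(stats$mu, stats2$mu)
  expect_identical(stats$sigma, stats2$sigma)
})

test_that("fold-specific statistics differ and match brute force", {
  ep <- random_epochs(12, seed = 5)
  f1 <- subset_epochs(ep, 1:8)
  f2 <- subset_epochs(ep, 5:12)
  s1 <- zscore_fit(f1)
  s2 <- zscore_fit(f2)
  expect_false(isTRUE(all.equal(s1$mu, s2$mu)))
  # brute-force oracle for one channel
  v <- as.vector(f1$data[3, , ])
  expect_equal(s1$mu[3], mean(v))
  expect_equal(s1$sigma[3], sd(v))
})

test_that("a zero-variance channel is reported by name", {
  ep <- random_epochs(4, seed = 6)
  ep$data[4, , ] <- 2
  expect_error(zscore_fit(ep), "Cz")
})

test_that("the printed normalization variant divides by the variance", {
  ep <- random_epochs(4, seed = 7)
  s_sd <- zscore_fit(ep)
  s_pr <- zscore_fit(ep, variant = "printed")
  a <- zscore_apply(ep, s_sd)
  b <- zscore_apply(ep, s_pr)
  expect_equal(b$data, a$data / rep(s_sd$sigma, 500 * 4), tolerance = 1e-12)
})

test_that("chunked causal filtering equals whole-stream filtering", {
  set.seed(8)
  x <- matrix(rnorm(8 * 10000) * 1e-5, 8, 10000)
  rec <- eeg_recording(x, 1000, SMR_CHANNELS)
  whole <- online_filter(rec)
  st <- online_filter_state(1000, n_channels = 8)
  pieces <- list()
  for (k in 1:10) {
    res <- online_filter_chunk(st, x[, ((k - 1) * 1000 + 1):(k * 1000)])
    st <- res$state
    pieces[[k]] <- res$y
  }
  expect_equal(do.call(cbind, pieces), unname(whole$signal), tolerance = 1e-9)
})

test_that("the causal 8-30 Hz path kills DC and passes 20 Hz", {
  dc <- eeg_recording(matrix(1e-5, 1, 4000), 1000, "C3")
  out <- online_filter(dc)
  expect_lt(max(abs(out$signal[1, 3000:4000])), 1e-10)

  tone <- tone_recording(20, fs = 1000, dur = 6, n_channels = 1)
  filt <- online_filter(tone)
  # oracle: the designed transfer function evaluated at 20 Hz
  bt <- signal::butter(3, c(8, 30) / 500, type = "pass")
  w <- 2 * pi * 20 / 1000
  zpow <- function(co) sum(co * exp(-1i * w * (seq_along(co) - 1)))
  gain_expected <- Mod(zpow(bt$b) / zpow(bt$a))
  mid <- 3001:6000
  gain_measured <- sqrt(mean(filt$signal[1, mid]^2) / mean(tone$signal[1, mid]^2))
  expect_equal(gain_measured, gain_expected, tolerance = 0.02)
})

test_that("sliding windows enumerate starts at the step size", {
  rec <- tone_recording(10, fs = 1000, dur = 4, n_channels = 2)
  sw <- sliding_windows(rec)
  # oracle: start times 0, 0.1, ..., 2.0
  expect_equal(n_epochs(sw), 21)
  expect_equal(sw$meta$t0, seq(0, 2, by = 0.1), tolerance = 1e-9)
  # exactly one window for a stream of window length
  one <- sliding_windows(eeg_recording(matrix(0, 2, 2000), 1000, c("C3", "C4")))
  expect_equal(n_epochs(one), 1)
  # consecutive windows share 1.9 s of samples
  a <- sw$data[, , 1]
  b <- sw$data[, , 2]
  expect_identical(a[, 101:2000], b[, 1:1900])
  # shorter than a window: empty sequence
  none <- sliding_windows(eeg_recording(matrix(0, 2, 1500), 1000, c("C3", "C4")))
  expect_equal(n_epochs(none), 0)
})
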