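# shared fixture builders; everything is generated in code at test time

# small, fast simulator: 250 Hz keeps 2 s epochs at the model's 500 samples
# without a decimation step
tiny_sim_config <- function(seed = 21, ...) {
  sim_config(sampling_rate = 250, seed = seed, ...)
}

# reduced decoder used by simulation-based tests
tiny_model_config <- function(n_blocks = 1, dropout = 0.2, ...) {
  model_config(temporal_kernels = 8, spatial_kernels = 16, n_heads = 4,
               n_blocks = n_blocks, ffn_dim = 64, fc1 = 32, fc2 = 16,
               dropout = dropout, ...)
}

# minimal configuration for gradient checks: a few of everything
grad_check_config <- function() {
  model_config(n_channels = 2, n_samples = 30, temporal_kernels = 3,
               temporal_size = 5, spatial_kernels = 4, pool_size = 6,
               pool_stride = 4, n_blocks = 1, n_heads = 2, ffn_dim = 8,
               dropout = 0, fc1 = 6, fc2 = 5)
}

random_epochs <- function(n, n_channels = 8, n_samples = 500, rate = 250,
                          labels = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(labels)) labels <- sample(SMR_CLASSES, n, replace = TRUE)
  epoch_set(array(rnorm(n_channels * n_samples * n),
                  c(n_channels, n_samples, n)),
            labels, rate, SMR_CHANNELS[seq_len(n_channels)])
}

# a recording that is pure deterministic signal (no simulator), for filter
# and epoching tests
tone_recording <- function(freqs, fs = 1000, dur = 10, amp = 1e-5,
                           n_channels = 8, events = NULL) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  sig <- matrix(0, n_channels, length(t))
  for (f in freqs) sig <- sig + amp * sin(2 * pi * f * rep(t, each = n_channels))
  if (is.null(events)) events <- data.frame(onset = numeric(0),
                                            code = integer(0),
                                            class = character(0),
                                            kind = character(0))
  eeg_recording(sig, fs, SMR_CHANNELS[seq_len(n_channels)], events)
}

# navigate nested weight lists (gradient check)
weight_paths <- function(w, prefix = character()) {
  if (is.list(w)) {
    unlist(lapply(seq_along(w), function(i) {
      nm <- if (!is.null(names(w)) && nzchar(names(w)[i])) names(w)[i] else i
      weight_paths(w[[i]], c(prefix, nm))
    }), recursive = FALSE)
  } else list(prefix)
}
weight_get <- function(w, p) { for (k in p) w <- w[[k]]; w }
weight_set <- function(w, p, v) {
  if (length(p) == 1) { w[[p[[1]]]] <- v; w }
  else { w[[p[[1]]]] <- weight_set(w[[p[[1]]]], p[-1], v); w }
}
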