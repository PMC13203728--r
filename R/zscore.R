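#' Fit per-channel normalization statistics on training data
#'
#' Computes the per-channel mean and standard deviation over every sample of
#' every epoch in the *training* partition. The statistics are frozen and
#' applied unchanged to validation, test and online data, so no information
#' leaks across the partition boundary.
#'
#' The default divides by the standard deviation (z-score). The published
#' formula prints the variance in the denominator; that variant is available
#' as `variant = "printed"` for fidelity experiments.
#'
#' @param train an [epoch_set()] from the training partition only.
#' @param variant `"sd"` (z-score, default) or `"printed"` (divide by
#'   variance).
#' @return an object of class `norm_stats` with per-channel `mu`, `sigma`.
#' @export
zscore_fit <- function(train, variant = c("sd", "printed")) {
  variant <- match.arg(variant)
  if (n_epochs(train) == 0) stop("training set is empty")
  d <- dim(train$data)
  x <- matrix(aperm(train$data, c(2, 3, 1)), ncol = d[1])  # (samples*epochs) x channels
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  zero <- sigma <= 0
  if (any(zero)) {
    stop("zero-variance channel(s): ",
         paste(train$channel_names[zero], collapse = ", "))
  }
  structure(list(mu = mu, sigma = sigma, variant = variant,
                 channel_names = train$channel_names),
            class = "norm_stats")
}

#' Apply frozen normalization statistics to epochs
#'
#' @param epochs an [epoch_set()].
#' @param stats a `norm_stats` object from [zscore_fit()].
#' @return the normalized [epoch_set()].
#' @export
zscore_apply <- function(epochs, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (!identical(epochs$channel_names, stats$channel_names)) {
    stop("epoch channels do not match the fitted statistics")
  }
  denom <- if (stats$variant == "printed") stats$sigma^2 else stats$sigma
  out <- (epochs$data - stats$mu) / denom  # stats recycle over the channel axis
  epoch_set(out, epochs$labels, epochs$sampling_rate, epochs$channel_names,
            epochs$meta)
}
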