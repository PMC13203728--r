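#' CNN-Transformer decoder configuration
#'
#' Hyperparameters of the four-class decoder: a temporal convolution
#' (`temporal_kernels` kernels of size 1 x `temporal_size`, stride 1), a
#' spatial convolution collapsing the channel axis (`spatial_kernels` kernels
#' of size `n_channels` x 1), batch normalization and ELU after each,
#' average pooling (1 x `pool_size`, stride 1 x `pool_stride`), then
#' `n_blocks` pre-normalized multi-head self-attention encoder blocks
#' (`n_heads` heads on `d_model = spatial_kernels` features, feed-forward
#' width `ffn_dim`, residual connections), and a fully connected classifier
#' (`fc1` units with ELU, `fc2` units with ELU, `n_classes`-way softmax)
#' with dropout between layers.
#'
#' With the defaults (8 x 500 input, 20/40 kernels, pool 75/10) the token
#' sequence has length 41, so the flattened classifier input is
#' 41 x 40 = 1640.
#'
#' @param n_channels,n_samples input epoch geometry (default 8 x 500).
#' @param temporal_kernels,temporal_size temporal convolution (default 20
#'   kernels of length 25).
#' @param spatial_kernels spatial convolution kernel count; also the token
#'   width `d_model` (default 40).
#' @param pool_size,pool_stride average pooling (default 75 / 10).
#' @param n_blocks encoder depth N (default 3).
#' @param n_heads attention heads h (default 10); must divide `d_model`.
#' @param ffn_dim feed-forward hidden width (default 160).
#' @param dropout dropout probability p (default 0.5).
#' @param fc1,fc2 classifier hidden widths (defaults 126 and 16).
#' @param n_classes output classes (default 4).
#' @param use_residual,use_layernorm include residual connections and layer
#'   normalization in the encoder blocks (default TRUE; they are standard in
#'   this architecture lineage and a 3-block stack trains poorly without
#'   them, but both can be disabled for ablation).
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_channels = 8, n_samples = 500,
                         temporal_kernels = 20, temporal_size = 25,
                         spatial_kernels = 40,
                         pool_size = 75, pool_stride = 10,
                         n_blocks = 3, n_heads = 10, ffn_dim = 160,
                         dropout = 0.5, fc1 = 126, fc2 = 16, n_classes = 4,
                         use_residual = TRUE, use_layernorm = TRUE) {
  d_model <- spatial_kernels
  if (d_model %% n_heads != 0) {
    stop("d_model (= spatial_kernels = ", d_model,
         ") must be divisible by n_heads (", n_heads, ")")
  }
  conv_len <- n_samples - temporal_size + 1
  if (conv_len < pool_size) stop("pooling window exceeds convolution output")
  tokens <- (conv_len - pool_size) %/% pool_stride + 1
  structure(
    list(n_channels = n_channels, n_samples = n_samples,
         temporal_kernels = temporal_kernels, temporal_size = temporal_size,
         spatial_kernels = spatial_kernels, d_model = d_model,
         pool_size = pool_size, pool_stride = pool_stride,
         n_blocks = n_blocks, n_heads = n_heads, ffn_dim = ffn_dim,
         dropout = dropout, fc1 = fc1, fc2 = fc2, n_classes = n_classes,
         use_residual = use_residual, use_layernorm = use_layernorm,
         conv_len = conv_len, tokens = tokens,
         flatten = tokens * d_model),
    class = "model_config"
  )
}

#' Token sequence length implied by a model configuration
#' @param config a [model_config()].
#' @return integer sequence length after convolution and pooling.
#' @export
token_count <- function(config) config$tokens

#' Total trainable parameter count
#'
#' A pure function of the configuration: convolution weights and biases,
#' batch-norm affine pairs, per-block layer norms, Q/K/V/output projections
#' and feed-forward weights, and the classifier stack.
#'
#' @param config a [model_config()].
#' @return integer number of trainable parameters.
#' @export
param_count <- function(config) {
  cfg <- config
  d <- cfg$d_model
  conv <- cfg$temporal_kernels * cfg$temporal_size + cfg$temporal_kernels +
    2 * cfg$temporal_kernels +                                  # bn1
    cfg$spatial_kernels * cfg$temporal_kernels * cfg$n_channels +
    cfg$spatial_kernels + 2 * cfg$spatial_kernels               # bn2
  ln <- if (cfg$use_layernorm) 2 * d else 0
  block <- 2 * ln +
    4 * (d * d + d) +                                           # Wq,Wk,Wv,Wo
    d * cfg$ffn_dim + cfg$ffn_dim + cfg$ffn_dim * d + d         # FFN
  clf <- cfg$flatten * cfg$fc1 + cfg$fc1 +
    cfg$fc1 * cfg$fc2 + cfg$fc2 +
    cfg$fc2 * cfg$n_classes + cfg$n_classes
  conv + cfg$n_blocks * block + clf
}
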