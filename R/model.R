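# activation helpers ---------------------------------------------------------

elu <- function(x) {
  y <- elu_cpp(x)
  attributes(y) <- attributes(x)
  y
}
# ELU'(x) expressed through the output: 1 where y > 0, y + 1 elsewhere
elu_grad <- function(y) {
  g <- elu_grad_cpp(y)
  attributes(g) <- attributes(y)
  g
}

softmax_rows <- function(x) {
  x <- x - x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x)
  e / .rowSums(e, nrow(e), ncol(e))
}

# add a per-column bias / scale to a (rows x features) matrix
addrow <- function(M, b) M + rep(b, each = nrow(M))
mulcol <- function(M, v) M * rep(v, each = nrow(M))

# batch-norm + ELU stage over the columns of each row (row = feature
# channel); the heavy elementwise passes run in fused C++ kernels
bn_elu_stage <- function(Z, g, b, rm, rv, training, eps = 1e-5) {
  if (training) {
    st <- row_mean_var_cpp(Z)
    m <- ncol(Z)
    mu <- st$mu
    v <- st$var
    rm <- 0.9 * rm + 0.1 * mu
    rv <- 0.9 * rv + 0.1 * v * m / max(m - 1, 1)
  } else {
    mu <- rm
    v <- rv
  }
  sdinv <- 1 / sqrt(v + eps)
  be <- bn_elu_forward_cpp(Z, mu, sdinv, g, b)
  list(y = be$y, xhat = be$xhat, sdinv = sdinv, rm = rm, rv = rv)
}

# layer-norm across the features (columns) of each row
ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  sdinv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * sdinv
  list(y = addrow(mulcol(xhat, g), b), xhat = xhat, sdinv = sdinv)
}

ln_backward <- function(dY, xhat, sdinv, g) {
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- mulcol(dY, g)
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * sdinv
  list(dX = dX, dg = dg, db = db)
}

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

uinit <- function(nr, nc, fan_in) {
  bound <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}
uinit_vec <- function(n, fan_in) runif(n, -1 / sqrt(fan_in), 1 / sqrt(fan_in))

# average-pooling operator as a (conv_len x tokens) matrix
pool_matrix <- function(cfg) {
  P <- matrix(0, cfg$conv_len, cfg$tokens)
  for (u in seq_len(cfg$tokens)) {
    s <- (u - 1) * cfg$pool_stride + 1
    P[s:(s + cfg$pool_size - 1), u] <- 1 / cfg$pool_size
  }
  P
}

#' Initialize a CNN-Transformer decoder
#'
#' Creates a model with fan-in uniform weight initialization (U(-1/sqrt(n),
#' 1/sqrt(n)) for weights and biases), unit batch-norm/layer-norm scales, and
#' zeroed running statistics. Fully seed-controlled.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight draw.
#' @param class_levels class label ordering the output units correspond to.
#' @return an object of class `conformer_model` holding `config`, `weights`,
#'   batch-norm `running` statistics, `class_levels`, and a `norm_stats` slot
#'   (filled by the training pipeline so checkpoints carry their
#'   preprocessing statistics).
#' @export
conformer_init <- function(config, seed = 1L, class_levels = SMR_CLASSES) {
  stopifnot(inherits(config, "model_config"))
  if (length(class_levels) != config$n_classes) {
    stop("class_levels must have ", config$n_classes, " entries")
  }
  cfg <- config
  d <- cfg$d_model
  with_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(i) {
      list(ln1_g = rep(1, d), ln1_b = rep(0, d),
           Wq = uinit(d, d, d), bq = uinit_vec(d, d),
           Wk = uinit(d, d, d), bk = uinit_vec(d, d),
           Wv = uinit(d, d, d), bv = uinit_vec(d, d),
           Wo = uinit(d, d, d), bo = uinit_vec(d, d),
           ln2_g = rep(1, d), ln2_b = rep(0, d),
           W1 = uinit(d, cfg$ffn_dim, d), bf1 = uinit_vec(cfg$ffn_dim, d),
           W2 = uinit(cfg$ffn_dim, d, cfg$ffn_dim),
           bf2 = uinit_vec(d, cfg$ffn_dim))
    })
    weights <- list(
      Wt = uinit(cfg$temporal_kernels, cfg$temporal_size, cfg$temporal_size),
      bt = uinit_vec(cfg$temporal_kernels, cfg$temporal_size),
      g1 = rep(1, cfg$temporal_kernels), b1 = rep(0, cfg$temporal_kernels),
      Ws = uinit(cfg$spatial_kernels, cfg$temporal_kernels * cfg$n_channels,
                 cfg$temporal_kernels * cfg$n_channels),
      bs = uinit_vec(cfg$spatial_kernels,
                     cfg$temporal_kernels * cfg$n_channels),
      g2 = rep(1, cfg$spatial_kernels), b2 = rep(0, cfg$spatial_kernels),
      blocks = blocks,
      Wc1 = uinit(cfg$flatten, cfg$fc1, cfg$flatten),
      bc1 = uinit_vec(cfg$fc1, cfg$flatten),
      Wc2 = uinit(cfg$fc1, cfg$fc2, cfg$fc1),
      bc2 = uinit_vec(cfg$fc2, cfg$fc1),
      Wc3 = uinit(cfg$fc2, cfg$n_classes, cfg$fc2),
      bc3 = uinit_vec(cfg$n_classes, cfg$fc2))
    structure(
      list(config = cfg, weights = weights,
           running = list(m1 = rep(0, cfg$temporal_kernels),
                          v1 = rep(1, cfg$temporal_kernels),
                          m2 = rep(0, cfg$spatial_kernels),
                          v2 = rep(1, cfg$spatial_kernels)),
           class_levels = class_levels, norm_stats = NULL,
           version = "smrbci-checkpoint-1"),
      class = "conformer_model")
  })
}

#' @export
print.conformer_model <- function(x, ...) {
  cat(sprintf(
    "<conformer_model> %d ch x %d samples -> %d tokens x %d, %d block(s), %d head(s), %s parameters\n",
    x$config$n_channels, x$config$n_samples, x$config$tokens,
    x$config$d_model, x$config$n_blocks, x$config$n_heads,
    format(param_count(x$config), big.mark = ",")))
  invisible(x)
}
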