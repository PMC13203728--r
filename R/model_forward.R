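#' Forward pass of the CNN-Transformer decoder
#'
#' Runs normalized epochs through the convolutional front-end (temporal
#' convolution, batch norm, ELU; spatial convolution collapsing the channel
#' axis, batch norm, ELU; average pooling; dropout), the stacked
#' pre-normalized multi-head self-attention encoder blocks, and the fully
#' connected softmax classifier.
#'
#' In evaluation mode (`training = FALSE`, the default) batch norm uses its
#' running statistics and dropout is disabled, so the output is a
#' deterministic function of (weights, input). In training mode batch
#' statistics are used and dropout masks are drawn from the current RNG
#' stream; intermediate quantities are cached for [conformer_backward()].
#'
#' @param model a [conformer_init()] model.
#' @param X an [epoch_set()] or a channels x samples x batch array of
#'   *normalized* epochs.
#' @param training logical; training-mode forward (batch statistics,
#'   dropout, cache).
#' @param features logical; also return the flattened token features feeding
#'   the classifier (the self-attention module output; used for embedding
#'   visualizations).
#' @return a list with `probs` (batch x classes, rows on the simplex),
#'   `logits`, optionally `features`, and in training mode `cache`.
#' @export
conformer_forward <- function(model, X, training = FALSE, features = FALSE) {
  cfg <- model$config
  W <- model$weights
  if (inherits(X, "epoch_set")) X <- X$data
  d <- dim(X)
  if (length(d) != 3 || d[1] != cfg$n_channels || d[2] != cfg$n_samples) {
    stop(sprintf("input must be %d x %d x batch (got %s)",
                 cfg$n_channels, cfg$n_samples, paste(d, collapse = " x ")))
  }
  B <- d[3]
  C <- cfg$n_channels; L1 <- cfg$conv_len; ts <- cfg$temporal_size
  K1 <- cfg$temporal_kernels; K2 <- cfg$spatial_kernels
  U <- cfg$tokens; dm <- cfg$d_model; h <- cfg$n_heads; dk <- dm / h
  p <- if (training) cfg$dropout else 0

  # temporal convolution (valid padding) as one matrix product on the
  # unfolded input; columns ordered (channel, position, batch)
  M <- unfold_cpp(X, C, S <- cfg$n_samples, B, ts)
  Z1 <- W$Wt %*% M + W$bt
  bn1 <- bn_elu_stage(Z1, W$g1, W$b1, model$running$m1, model$running$v1,
                      training)
  A1 <- bn1$y

  # spatial convolution collapses (kernel, channel) into d_model features
  A2in <- A1
  dim(A2in) <- c(K1 * C, L1 * B)
  Z2 <- W$Ws %*% A2in + W$bs
  bn2 <- bn_elu_stage(Z2, W$g2, W$b2, model$running$m2, model$running$v2,
                      training)
  A2 <- bn2$y

  # average pooling, then reshape to a (tokens*batch) x d_model matrix with
  # rows ordered (token, batch)
  P <- pool_matrix(cfg)
  A2arr <- array(A2, c(K2, L1, B))
  pooled <- matrix(aperm(A2arr, c(1, 3, 2)), K2 * B, L1) %*% P
  Tk <- matrix(aperm(array(pooled, c(K2, B, U)), c(3, 2, 1)), U * B, dm)
  mask0 <- dropout_mask(U * B, dm, p)
  if (!is.null(mask0)) Tk <- Tk * mask0

  blocks_cache <- vector("list", cfg$n_blocks)
  for (blk in seq_len(cfg$n_blocks)) {
    Wb <- W$blocks[[blk]]
    Tk_in <- Tk
    if (cfg$use_layernorm) {
      ln1 <- ln_forward(Tk_in, Wb$ln1_g, Wb$ln1_b)
      X1 <- ln1$y
    } else {
      ln1 <- NULL
      X1 <- Tk_in
    }
    Q <- addrow(X1 %*% Wb$Wq, Wb$bq)
    K <- addrow(X1 %*% Wb$Wk, Wb$bk)
    V <- addrow(X1 %*% Wb$Wv, Wb$bv)
    Ctx <- matrix(0, U * B, dm)
    Aatt <- array(0, c(U, U, h, B))
    for (b in seq_len(B)) {
      rows <- ((b - 1) * U + 1):(b * U)
      for (l in seq_len(h)) {
        cols <- ((l - 1) * dk + 1):(l * dk)
        S <- tcrossprod(Q[rows, cols, drop = FALSE],
                        K[rows, cols, drop = FALSE]) / sqrt(dk)
        A <- softmax_rows(S)
        Aatt[, , l, b] <- A
        Ctx[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      }
    }
    O <- addrow(Ctx %*% Wb$Wo, Wb$bo)
    maskA <- dropout_mask(U * B, dm, p)
    if (!is.null(maskA)) O <- O * maskA
    Tk_mid <- if (cfg$use_residual) Tk_in + O else O

    if (cfg$use_layernorm) {
      ln2 <- ln_forward(Tk_mid, Wb$ln2_g, Wb$ln2_b)
      X2 <- ln2$y
    } else {
      ln2 <- NULL
      X2 <- Tk_mid
    }
    H1pre <- addrow(X2 %*% Wb$W1, Wb$bf1)
    H1 <- elu(H1pre)
    Fo <- addrow(H1 %*% Wb$W2, Wb$bf2)
    maskF <- dropout_mask(U * B, dm, p)
    if (!is.null(maskF)) Fo <- Fo * maskF
    Tk <- if (cfg$use_residual) Tk_mid + Fo else Fo

    blocks_cache[[blk]] <- list(ln1 = ln1, X1 = X1, Q = Q, K = K, V = V,
                                Aatt = Aatt, Ctx = Ctx, maskA = maskA,
                                ln2 = ln2, X2 = X2, H1 = H1, maskF = maskF)
  }

  # flatten (token, feature) per batch element: feature order token-fastest
  Fl <- t(matrix(aperm(array(Tk, c(U, B, dm)), c(1, 3, 2)), U * dm, B))
  G1pre <- addrow(Fl %*% W$Wc1, W$bc1)
  E1 <- elu(G1pre)
  mfc1 <- dropout_mask(B, cfg$fc1, p)
  G1 <- if (is.null(mfc1)) E1 else E1 * mfc1
  G2pre <- addrow(G1 %*% W$Wc2, W$bc2)
  E2 <- elu(G2pre)
  mfc2 <- dropout_mask(B, cfg$fc2, p)
  G2 <- if (is.null(mfc2)) E2 else E2 * mfc2
  logits <- addrow(G2 %*% W$Wc3, W$bc3)
  probs <- softmax_rows(logits)

  out <- list(probs = probs, logits = logits)
  if (features) out$features <- Fl
  if (training) {
    out$cache <- list(
      B = B, M = M, bn1 = bn1, A1 = A1, bn2 = bn2, A2 = A2, P = P,
      mask0 = mask0, blocks = blocks_cache, Fl = Fl,
      E1 = E1, mfc1 = mfc1, G1 = G1, E2 = E2, mfc2 = mfc2, G2 = G2,
      probs = probs)
  }
  out
}

#' Backward pass (hand-derived gradients)
#'
#' Given the training-mode cache from [conformer_forward()] and the gradient
#' of the loss with respect to the logits, computes gradients for every
#' trainable tensor by reverse accumulation through the classifier, the
#' encoder stack (attention softmax, per-head projections, layer norms,
#' residuals, feed-forward), pooling, both batch norms and both
#' convolutions. Verified against central finite differences in the test
#' suite.
#'
#' @param model a `conformer_model`.
#' @param cache the `cache` element of a training-mode forward pass.
#' @param dlogits batch x classes gradient of the loss w.r.t. the logits
#'   (for mean cross-entropy: `(probs - onehot) / batch`).
#' @return a list of gradients with the same structure as `model$weights`.
#' @export
conformer_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  W <- model$weights
  B <- cache$B
  C <- cfg$n_channels; L1 <- cfg$conv_len
  K1 <- cfg$temporal_kernels; K2 <- cfg$spatial_kernels
  U <- cfg$tokens; dm <- cfg$d_model; h <- cfg$n_heads; dk <- dm / h
  g <- list()

  # classifier
  g$Wc3 <- crossprod(cache$G2, dlogits)
  g$bc3 <- colSums(dlogits)
  dG2 <- tcrossprod(dlogits, W$Wc3)
  dE2 <- if (is.null(cache$mfc2)) dG2 else dG2 * cache$mfc2
  dG2pre <- dE2 * elu_grad(cache$E2)
  g$Wc2 <- crossprod(cache$G1, dG2pre)
  g$bc2 <- colSums(dG2pre)
  dG1 <- tcrossprod(dG2pre, W$Wc2)
  dE1 <- if (is.null(cache$mfc1)) dG1 else dG1 * cache$mfc1
  dG1pre <- dE1 * elu_grad(cache$E1)
  g$Wc1 <- crossprod(cache$Fl, dG1pre)
  g$bc1 <- colSums(dG1pre)
  dFl <- tcrossprod(dG1pre, W$Wc1)

  # unflatten to (token*batch) x d_model
  dTk <- matrix(aperm(array(t(dFl), c(U, dm, B)), c(1, 3, 2)), U * B, dm)

  g$blocks <- vector("list", cfg$n_blocks)
  for (blk in rev(seq_len(cfg$n_blocks))) {
    Wb <- W$blocks[[blk]]
    cb <- cache$blocks[[blk]]
    gb <- list()

    # feed-forward sub-layer
    dF <- if (is.null(cb$maskF)) dTk else dTk * cb$maskF
    gb$bf2 <- colSums(dF)
    gb$W2 <- crossprod(cb$H1, dF)
    dH1 <- tcrossprod(dF, Wb$W2)
    dH1pre <- dH1 * elu_grad(cb$H1)
    gb$bf1 <- colSums(dH1pre)
    gb$W1 <- crossprod(cb$X2, dH1pre)
    dX2 <- tcrossprod(dH1pre, Wb$W1)
    if (cfg$use_layernorm) {
      lb <- ln_backward(dX2, cb$ln2$xhat, cb$ln2$sdinv, Wb$ln2_g)
      gb$ln2_g <- lb$dg; gb$ln2_b <- lb$db
      dTk_mid <- lb$dX
    } else {
      dTk_mid <- dX2
    }
    if (cfg$use_residual) dTk_mid <- dTk_mid + dTk

    # attention sub-layer
    dO <- if (is.null(cb$maskA)) dTk_mid else dTk_mid * cb$maskA
    gb$bo <- colSums(dO)
    gb$Wo <- crossprod(cb$Ctx, dO)
    dCtx <- tcrossprod(dO, Wb$Wo)
    dQ <- matrix(0, U * B, dm)
    dK <- matrix(0, U * B, dm)
    dV <- matrix(0, U * B, dm)
    for (b in seq_len(B)) {
      rows <- ((b - 1) * U + 1):(b * U)
      for (l in seq_len(h)) {
        cols <- ((l - 1) * dk + 1):(l * dk)
        A <- cb$Aatt[, , l, b]
        dCtx_bl <- dCtx[rows, cols, drop = FALSE]
        Vbl <- cb$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dCtx_bl, Vbl)
        dV[rows, cols] <- crossprod(A, dCtx_bl)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rows, cols] <- dS %*% cb$K[rows, cols, drop = FALSE] / sqrt(dk)
        dK[rows, cols] <- crossprod(dS, cb$Q[rows, cols, drop = FALSE]) / sqrt(dk)
      }
    }
    gb$Wq <- crossprod(cb$X1, dQ); gb$bq <- colSums(dQ)
    gb$Wk <- crossprod(cb$X1, dK); gb$bk <- colSums(dK)
    gb$Wv <- crossprod(cb$X1, dV); gb$bv <- colSums(dV)
    dX1 <- tcrossprod(dQ, Wb$Wq) + tcrossprod(dK, Wb$Wk) +
      tcrossprod(dV, Wb$Wv)
    if (cfg$use_layernorm) {
      lb <- ln_backward(dX1, cb$ln1$xhat, cb$ln1$sdinv, Wb$ln1_g)
      gb$ln1_g <- lb$dg; gb$ln1_b <- lb$db
      dTk <- lb$dX
    } else {
      dTk <- dX1
    }
    if (cfg$use_residual) dTk <- dTk + dTk_mid
    if (!cfg$use_layernorm) {
      # layer-norm parameters exist but are unused; zero gradients keep the
      # optimizer structure aligned
      gb$ln1_g <- gb$ln2_g <- Wb$ln1_g * 0
      gb$ln1_b <- gb$ln2_b <- Wb$ln1_b * 0
    }
    g$blocks[[blk]] <- gb[names(W$blocks[[blk]])]
  }

  if (!is.null(cache$mask0)) dTk <- dTk * cache$mask0

  # pooling backward
  dpooled <- matrix(aperm(array(dTk, c(U, B, dm)), c(3, 2, 1)), K2 * B, U)
  dA2blk <- tcrossprod(dpooled, cache$P)                 # (K2*B) x L1
  dA2 <- matrix(aperm(array(dA2blk, c(K2, B, L1)), c(1, 3, 2)), K2, L1 * B)

  # spatial conv + bn2 (fused ELU + batch-norm backward)
  bb2 <- bn_elu_backward_cpp(dA2, cache$A2, cache$bn2$xhat, cache$bn2$sdinv,
                             W$g2)
  g$g2 <- bb2$dg; g$b2 <- bb2$db
  dZ2 <- bb2$dZ
  A2in <- cache$A1
  dim(A2in) <- c(K1 * C, L1 * B)
  g$Ws <- tcrossprod(dZ2, A2in)
  g$bs <- rowSums(dZ2)
  dA2in <- crossprod(W$Ws, dZ2)
  dA1 <- dA2in
  dim(dA1) <- c(K1, C * L1 * B)

  # temporal conv + bn1
  dA1m <- dA1
  bb1 <- bn_elu_backward_cpp(dA1m, cache$A1, cache$bn1$xhat, cache$bn1$sdinv,
                             W$g1)
  g$g1 <- bb1$dg; g$b1 <- bb1$db
  dZ1 <- bb1$dZ
  g$Wt <- tcrossprod(dZ1, cache$M)
  g$bt <- rowSums(dZ1)

  # return in the same order as model$weights
  g[names(model$weights)]
}

#' Scaled dot-product attention
#'
#' The attention primitive used inside every head:
#' `softmax(Q K' / sqrt(k)) V` with row-wise softmax, where `k` is the key
#' width. Exposed for testing and for building attention variants.
#'
#' @param Q,K,V query/key/value matrices with equal row counts; `Q` and `K`
#'   share the key width `k`.
#' @return the context matrix (same shape as `V`), with the attention weight
#'   matrix attached as attribute `"weights"`.
#' @export
scaled_attention <- function(Q, K, V) {
  stopifnot(nrow(Q) == nrow(K), nrow(K) == nrow(V), ncol(Q) == ncol(K))
  A <- softmax_rows(tcrossprod(Q, K) / sqrt(ncol(K)))
  structure(A %*% V, weights = A)
}

#' Multi-head self-attention on a token sequence
#'
#' Splits the projected queries, keys and values into `n_heads` contiguous
#' groups, runs [scaled_attention()] per head, concatenates the head outputs
#' and applies the output projection. This is the standalone (single
#' sequence) form of the attention used inside the encoder blocks.
#'
#' @param x tokens x d_model matrix.
#' @param Wq,Wk,Wv,Wo d_model x d_model projection matrices.
#' @param bq,bk,bv,bo projection biases.
#' @param n_heads number of heads; must divide d_model.
#' @return tokens x d_model context matrix.
#' @export
multi_head_attention <- function(x, Wq, Wk, Wv, Wo, bq, bk, bv, bo, n_heads) {
  dm <- ncol(x)
  if (dm %% n_heads != 0) {
    stop("d_model (", dm, ") must be divisible by n_heads (", n_heads, ")")
  }
  dk <- dm / n_heads
  Q <- addrow(x %*% Wq, bq)
  K <- addrow(x %*% Wk, bk)
  V <- addrow(x %*% Wv, bv)
  Ctx <- matrix(0, nrow(x), dm)
  for (l in seq_len(n_heads)) {
    cols <- ((l - 1) * dk + 1):(l * dk)
    Ctx[, cols] <- scaled_attention(Q[, cols, drop = FALSE],
                                    K[, cols, drop = FALSE],
                                    V[, cols, drop = FALSE])
  }
  addrow(Ctx %*% Wo, bo)
}
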