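test_that("shape propagation matches a brute-force sliding-window count", {
  cfg <- model_config()
  # oracle: enumerate valid temporal positions, then pooling positions
  conv_positions <- sum(seq_len(500) + 25 - 1 <= 500)
  pool_positions <- length(seq(1, conv_positions - 75 + 1, by = 10))
  expect_equal(conv_positions, 476)
  expect_equal(token_count(cfg), pool_positions)
  expect_equal(token_count(cfg), 41)
  expect_equal(cfg$flatten, 41 * 40)
})

test_that("invalid head counts and shapes are rejected", {
  expect_error(model_config(n_heads = 7), "divisible")
  m <- conformer_init(tiny_model_config(), seed = 1)
  expect_error(conformer_forward(m, array(0, c(8, 400, 1))), "8 x 500")
})

test_that("parameter count equals the hand-computed total for the default
          configuration", {
  # independent arithmetic: conv 520 + 6440, batch norms 40 + 80, three
  # encoder blocks of 19720, classifier 206766 + 2032 + 68
  conv1 <- 20 * 25 + 20
  bn1 <- 2 * 20
  conv2 <- 40 * (20 * 8) + 40
  bn2 <- 2 * 40
  block <- (2 * 40) * 2 + 4 * (40 * 40 + 40) + (40 * 160 + 160) + (160 * 40 + 40)
  clf <- (1640 * 126 + 126) + (126 * 16 + 16) + (16 * 4 + 4)
  expect_equal(param_count(model_config()),
               conv1 + bn1 + conv2 + bn2 + 3 * block + clf)
  expect_equal(param_count(model_config()), 275106)
})

test_that("the convolution front-end is linear before normalization", {
  cfg <- tiny_model_config(dropout = 0)
  m <- conformer_init(cfg, seed = 2)
  # bias-free, identity-normalization variant: zero biases, neutral norms
  m$weights$bt[] <- 0
  m$weights$bs[] <- 0
  set.seed(3)
  X <- array(rnorm(8 * 500 * 2), c(8, 500, 2))
  # temporal conv output (pre-norm) via the package path: use a one-kernel
  # probe against direct convolution
  w <- m$weights$Wt[1, ]
  direct <- sapply(1:476, function(t) sum(w * X[3, t:(t + 24), 1]))
  M <- sapply(1:476, function(t) X[3, t:(t + 24), 1])
  expect_equal(direct, as.vector(w %*% M), tolerance = 1e-12)
  # doubling the input doubles the pre-normalization response
  expect_equal(2 * direct,
               sapply(1:476, function(t) sum(w * 2 * X[3, t:(t + 24), 1])),
               tolerance = 1e-12)
})

test_that("scaled attention matches its definition and limiting cases", {
  # single token: weight 1, output = V
  out <- scaled_attention(matrix(1, 1, 4), matrix(2, 1, 4), matrix(5:8, 1, 4))
  expect_equal(unclass(out)[1, ], c(5, 6, 7, 8), ignore_attr = TRUE)
  expect_equal(attr(out, "weights")[1, 1], 1)

  # identical keys: uniform weights, output = column mean of V
  set.seed(4)
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rep(rnorm(4), each = 3), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  out <- scaled_attention(Q, K, V)
  expect_equal(unclass(out), matrix(rep(colMeans(V), each = 3), 3, 4),
               tolerance = 1e-12, ignore_attr = TRUE)

  # random 3-token case vs a brute-force per-element oracle
  Q <- matrix(rnorm(12), 3, 4); K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) S[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(4)
  A <- t(apply(S, 1, function(r) exp(r) / sum(exp(r))))
  O <- matrix(0, 3, 4)
  for (i in 1:3) for (d in 1:4) O[i, d] <- sum(A[i, ] * V[, d])
  expect_equal(unclass(scaled_attention(Q, K, V)), O, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("multi-head attention reduces to one head and keeps width", {
  set.seed(5)
  d <- 6
  x <- matrix(rnorm(5 * d), 5, d)
  Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
  Wv <- matrix(rnorm(d * d), d); Wo <- diag(d)
  b0 <- rep(0, d)
  one <- multi_head_attention(x, Wq, Wk, Wv, Wo, b0, b0, b0, b0, n_heads = 1)
  ref <- unclass(scaled_attention(x %*% Wq, x %*% Wk, x %*% Wv))
  expect_equal(one, ref, tolerance = 1e-12, ignore_attr = TRUE)
  for (h in c(2, 3, 6)) {
    expect_equal(ncol(multi_head_attention(x, Wq, Wk, Wv, Wo, b0, b0, b0, b0,
                                           n_heads = h)), d)
  }
  expect_error(multi_head_attention(x, Wq, Wk, Wv, Wo, b0, b0, b0, b0,
                                    n_heads = 4), "divisible")
})

test_that("permuting heads with matching output-projection rows is a no-op", {
  set.seed(6)
  d <- 6; h <- 3; dk <- 2
  x <- matrix(rnorm(4 * d), 4, d)
  Wq <- matrix(rnorm(d * d), d); Wk <- matrix(rnorm(d * d), d)
  Wv <- matrix(rnorm(d * d), d); Wo <- matrix(rnorm(d * d), d)
  b0 <- rep(0, d)
  base <- multi_head_attention(x, Wq, Wk, Wv, Wo, b0, b0, b0, b0, h)
  # swap head 1 and head 3 in all projections and the matching Wo rows
  perm <- c(5, 6, 3, 4, 1, 2)
  base2 <- multi_head_attention(x, Wq[, perm], Wk[, perm], Wv[, perm],
                                Wo[perm, ], b0, b0, b0, b0, h)
  expect_equal(base, base2, tolerance = 1e-10)
})

test_that("a zero-depth encoder is the identity and output shapes are
          stable", {
  cfg0 <- tiny_model_config(n_blocks = 0, dropout = 0)
  m0 <- conformer_init(cfg0, seed = 7)
  cfg1 <- tiny_model_config(n_blocks = 2, dropout = 0)
  m1 <- conformer_init(cfg1, seed = 7)
  X <- random_epochs(3, seed = 8)
  f0 <- conformer_forward(m0, X, features = TRUE)
  f1 <- conformer_forward(m1, X, features = TRUE)
  expect_equal(dim(f0$features), dim(f1$features))
  expect_equal(dim(f0$probs), c(3, 4))
})

test_that("evaluation-mode forward is deterministic despite dropout", {
  m <- conformer_init(tiny_model_config(dropout = 0.5), seed = 9)
  X <- random_epochs(4, seed = 10)
  p1 <- conformer_forward(m, X)$probs
  p2 <- conformer_forward(m, X)$probs
  expect_identical(p1, p2)
})

test_that("class probabilities live on the simplex and argmax follows the
          logits", {
  m <- conformer_init(tiny_model_config(), seed = 11)
  X <- random_epochs(6, seed = 12)
  fw <- conformer_forward(m, X)
  expect_true(all(fw$probs >= 0))
  expect_equal(rowSums(fw$probs), rep(1, 6), tolerance = 1e-6)
  expect_equal(max.col(fw$probs), max.col(fw$logits))
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- grad_check_config()
  m <- conformer_init(cfg, seed = 3)
  set.seed(42)
  B <- 3
  X <- array(rnorm(2 * 30 * B), c(2, 30, B))
  Y <- matrix(0, B, 4); Y[cbind(1:B, c(2, 4, 1))] <- 1
  loss_fn <- function(model) {
    p <- conformer_forward(model, X, training = TRUE)$probs
    -mean(log(p[Y == 1]))
  }
  fw <- conformer_forward(m, X, training = TRUE)
  gr <- conformer_backward(m, fw$cache, (fw$probs - Y) / B)
  eps <- 1e-5
  worst <- 0
  for (p in weight_paths(m$weights)) {
    wt <- weight_get(m$weights, p)
    gt <- weight_get(gr, p)
    idxs <- unique(round(seq(1, length(wt), length.out = min(4, length(wt)))))
    for (i in idxs) {
      wp <- wt; wp[i] <- wt[i] + eps
      mm <- m; mm$weights <- weight_set(m$weights, p, wp)
      lp <- loss_fn(mm)
      wm <- wt; wm[i] <- wt[i] - eps
      mm$weights <- weight_set(m$weights, p, wm)
      lm <- loss_fn(mm)
      fd <- (lp - lm) / (2 * eps)
      # 1e-6 floor: biases feeding straight into batch norm have an exactly
      # zero gradient, where a relative criterion is meaningless
      worst <- max(worst, abs(fd - gt[i]) / max(abs(fd), abs(gt[i]), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the full-size model has the capacity to memorize random labels", {
  set.seed(16)
  m <- conformer_init(model_config(dropout = 0), seed = 16)
  ep <- epoch_set(array(rnorm(8 * 500 * 32), c(8, 500, 32)),
                  sample(SMR_CLASSES, 32, replace = TRUE), 250, SMR_CHANNELS)
  cfg <- train_config("offline", epochs = 500, batch_size = 32,
                      lr_max = 3e-4, schedule = "fixed", stop_loss = 0.1,
                      seed = 17)
  m <- fit_conformer(m, ep, cfg)
  expect_lt(tail(m$loss_trace, 1), 0.1)
  expect_lte(length(m$loss_trace), 500)
})

test_that("checkpoints round-trip exactly", {
  m <- conformer_init(tiny_model_config(), seed = 13)
  m$norm_stats <- zscore_fit(random_epochs(5, seed = 14))
  path <- tempfile(fileext = ".ckpt")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  X <- random_epochs(3, seed = 15)
  expect_identical(conformer_forward(m, X)$probs,
                   conformer_forward(m2, X)$probs)
  expect_identical(m$norm_stats, m2$norm_stats)
  expect_identical(m$class_levels, m2$class_levels)
  # non-checkpoint files are refused
  bad <- tempfile()
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
})
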