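#' Training configuration
#'
#' Optimizer and schedule settings for the two training phases. Offline
#' pre-training: 100 epochs, batch 100, base learning rate 3e-4 under a
#' warm-up (10 epochs) plus linear-decay schedule. Online fine-tuning: 20
#' epochs, batch 16, fixed learning rate 2e-5. Both phases use Adam with
#' beta1 = 0.5, beta2 = 0.999 and weight decay 1e-4 on the cross-entropy
#' loss.
#'
#' @param phase `"offline"` or `"online"`; selects the default block.
#' @param epochs,batch_size,lr_max,n_warmup,schedule,beta1,beta2,weight_decay
#'   individual overrides of the phase defaults.
#' @param stop_loss optional early-stopping threshold: training ends after
#'   the first epoch whose mean loss falls below it.
#' @param seed integer seed controlling shuffling and dropout.
#' @return an object of class `train_config`.
#' @export
train_config <- function(phase = c("offline", "online"),
                         epochs = NULL, batch_size = NULL, lr_max = NULL,
                         n_warmup = NULL, schedule = NULL,
                         beta1 = 0.5, beta2 = 0.999, weight_decay = 1e-4,
                         stop_loss = NULL, seed = 1L) {
  phase <- match.arg(phase)
  def <- if (phase == "offline") {
    list(epochs = 100, batch_size = 100, lr_max = 3e-4, n_warmup = 10,
         schedule = "warmup_linear")
  } else {
    list(epochs = 20, batch_size = 16, lr_max = 2e-5, n_warmup = NA,
         schedule = "fixed")
  }
  structure(
    list(phase = phase,
         epochs = epochs %||% def$epochs,
         batch_size = batch_size %||% def$batch_size,
         lr_max = lr_max %||% def$lr_max,
         n_warmup = n_warmup %||% def$n_warmup,
         schedule = schedule %||% def$schedule,
         beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
         stop_loss = stop_loss, seed = as.integer(seed)),
    class = "train_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Warm-up / linear-decay learning-rate schedule
#'
#' For 1-based epoch index e: `lr_max * e / n_warmup` while `e <= n_warmup`,
#' then `lr_max * (n_epoch - e) / (n_epoch - n_warmup)`. The two branches
#' meet at `lr_max` at `e = n_warmup`; the rate is exactly 0 at
#' `e = n_epoch` (the final epoch still runs, contributing no update).
#'
#' @param epoch 1-based epoch index in `[1, n_epoch]`.
#' @param lr_max base (peak) learning rate.
#' @param n_warmup warm-up length in epochs; must be `< n_epoch`.
#' @param n_epoch total number of epochs.
#' @return the learning rate for that epoch.
#' @export
lr_at_epoch <- function(epoch, lr_max, n_warmup, n_epoch) {
  if (any(epoch < 1 | epoch > n_epoch)) {
    stop("epoch must lie in [1, ", n_epoch, "]")
  }
  if (n_warmup >= n_epoch) stop("n_warmup must be smaller than n_epoch")
  ifelse(epoch <= n_warmup,
         lr_max * epoch / n_warmup,
         lr_max * (n_epoch - epoch) / (n_epoch - n_warmup))
}

# Adam with L2-coupled weight decay, applied tensor-wise over the nested
# weight list. `state` holds first/second moments in parallel structures.
adam_init <- function(weights) {
  zero_like <- function(w) {
    if (is.list(w)) lapply(w, zero_like) else w * 0
  }
  list(m = zero_like(weights), v = zero_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1, beta2, wd,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(w, g, m, v) {
    if (is.list(w)) {
      out_w <- w; out_m <- m; out_v <- v
      for (i in seq_along(w)) {
        r <- rec(w[[i]], g[[i]], m[[i]], v[[i]])
        out_w[[i]] <- r[[1]]; out_m[[i]] <- r[[2]]; out_v[[i]] <- r[[3]]
      }
      list(out_w, out_m, out_v)
    } else {
      g <- g + wd * w
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mh <- m / (1 - beta1^t)
      vh <- v / (1 - beta2^t)
      list(w - lr * mh / (sqrt(vh) + eps), m, v)
    }
  }
  r <- rec(weights, grads, state$m, state$v)
  list(weights = r[[1]], state = list(m = r[[2]], v = r[[3]], t = t))
}

one_hot <- function(labels, levels) {
  idx <- match(labels, levels)
  if (anyNA(idx)) {
    stop("unknown label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  }
  Y <- matrix(0, length(idx), length(levels))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

#' Fit the decoder by minibatch gradient descent
#'
#' Optimizes the mean cross-entropy with Adam over shuffled minibatches (the
#' final short batch is kept). The learning rate follows the configured
#' schedule; batch-norm running statistics are updated each step. Fully
#' reproducible under `config$seed`. Training aborts with diagnostics if the
#' loss becomes non-finite.
#'
#' @param model a `conformer_model`.
#' @param train an [epoch_set()] of normalized training epochs with labels
#'   drawn from `model$class_levels`.
#' @param config a [train_config()].
#' @param verbose print per-epoch loss.
#' @return the trained model, with the per-epoch mean loss trace attached as
#'   `model$loss_trace`.
#' @export
fit_conformer <- function(model, train, config = train_config("offline"),
                          verbose = FALSE) {
  stopifnot(inherits(model, "conformer_model"), inherits(train, "epoch_set"))
  n <- n_epochs(train)
  if (n == 0) stop("training set is empty")
  Y_all <- one_hot(train$labels, model$class_levels)
  X_all <- train$data
  trace <- numeric(config$epochs)
  with_seed(config$seed, {
    opt <- adam_init(model$weights)
    for (ep in seq_len(config$epochs)) {
      lr <- if (config$schedule == "warmup_linear") {
        lr_at_epoch(ep, config$lr_max, config$n_warmup, config$epochs)
      } else {
        config$lr_max
      }
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1, n)]
        Xb <- X_all[, , idx, drop = FALSE]
        Yb <- Y_all[idx, , drop = FALSE]
        fw <- conformer_forward(model, Xb, training = TRUE)
        pb <- fw$probs
        loss <- -mean(log(pmax(pb[Yb == 1], 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d, batch %d (lr %.2e)",
                       ep, bi, lr))
        }
        losses[bi] <- loss
        model$running$m1 <- fw$cache$bn1$rm
        model$running$v1 <- fw$cache$bn1$rv
        model$running$m2 <- fw$cache$bn2$rm
        model$running$v2 <- fw$cache$bn2$rv
        if (lr > 0) {
          dlogits <- (pb - Yb) / nrow(Yb)
          grads <- conformer_backward(model, fw$cache, dlogits)
          st <- adam_step(model$weights, grads, opt, lr,
                          config$beta1, config$beta2, config$weight_decay)
          model$weights <- st$weights
          opt <- st$state
        }
      }
      trace[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f", ep, lr, trace[ep]))
      }
      if (!is.null(config$stop_loss) && trace[ep] < config$stop_loss) {
        trace <- trace[seq_len(ep)]
        break
      }
    }
  })
  model$loss_trace <- trace
  model
}

#' Class probabilities / labels for new epochs
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no dropout).
#' If the model carries `norm_stats`, raw epochs are normalized with them
#' first; pass normalized epochs and `normalize = FALSE` to skip.
#'
#' @param model a `conformer_model`.
#' @param epochs an [epoch_set()] or channels x samples x batch array.
#' @param normalize apply the checkpoint's normalization statistics first.
#' @return `predict_proba`: batch x classes probability matrix;
#'   `predict_classes`: character vector of predicted labels.
#' @export
predict_proba <- function(model, epochs, normalize = !is.null(model$norm_stats)) {
  if (normalize) {
    if (is.null(model$norm_stats)) stop("model carries no norm_stats")
    epochs <- zscore_apply(epochs, model$norm_stats)
  }
  conformer_forward(model, epochs, training = FALSE)$probs
}

#' @rdname predict_proba
#' @export
predict_classes <- function(model, epochs, normalize = !is.null(model$norm_stats)) {
  p <- predict_proba(model, epochs, normalize)
  model$class_levels[max.col(p, ties.method = "first")]
}

#' Save / load a decoder checkpoint
#'
#' One versioned file holding the weights, the model configuration, the
#' preprocessing normalization statistics and the class ordering; the
#' round-trip is exact (identical forward passes).
#'
#' @param model a `conformer_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `conformer_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "conformer_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "conformer_model") ||
      !identical(model$version, "smrbci-checkpoint-1")) {
    stop("not a recognized smrbci checkpoint: ", path)
  }
  model
}
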