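# Exact t-SNE for small feature sets (hundreds of points), as used for the
# qualitative latent-space views: PCA initialization and a fixed seed give
# reproducible coordinates; perplexity defaults to 20.

# per-point precision search so each conditional distribution hits the
# target perplexity
tsne_p_matrix <- function(D2, perplexity, tol = 1e-5, max_iter = 50) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p == 0) p <- rep(1e-12, length(di)) else p <- p / sum_p
      h <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(h - target) < tol) break
      if (h > target) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Two-dimensional t-SNE embedding of feature vectors
#'
#' Exact (non-approximate) t-distributed stochastic neighbor embedding with
#' PCA initialization and momentum gradient descent, suitable for the few
#' hundred penultimate-feature vectors produced per session. With a fixed
#' seed the coordinates are bit-reproducible across runs.
#'
#' @param X points x features matrix.
#' @param perplexity neighborhood size parameter (default 20; must be less
#'   than (points - 1) / 3).
#' @param seed integer seed.
#' @param n_iter gradient-descent iterations (default 400).
#' @param learning_rate step size (default 100).
#' @return points x 2 matrix of embedding coordinates.
#' @export
tsne_embed <- function(X, perplexity = 20, seed = 1L, n_iter = 400,
                       learning_rate = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 points")
  if (perplexity >= (n - 1) / 3) {
    stop("perplexity too large for ", n, " points")
  }
  with_seed(seed, {
    pc <- prcomp(X, rank. = 2)
    # sign-stabilize the PCA so initialization is deterministic
    for (j in 1:2) {
      k <- which.max(abs(pc$rotation[, j]))
      if (pc$rotation[k, j] < 0) pc$x[, j] <- -pc$x[, j]
    }
    Y <- pc$x[, 1:2, drop = FALSE]
    Y <- Y / stats::sd(Y) * 1e-4
    P <- tsne_p_matrix(as.matrix(dist(X))^2, perplexity)
    gains <- matrix(1, n, 2)
    inc <- matrix(0, n, 2)
    for (it in seq_len(n_iter)) {
      exaggeration <- if (it <= 100) 12 else 1
      momentum <- if (it <= 250) 0.5 else 0.8
      num <- 1 / (1 + as.matrix(dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (exaggeration * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      inc <- momentum * inc - learning_rate * gains * grad
      Y <- Y + inc
      Y <- sweep(Y, 2, colMeans(Y))
    }
    colnames(Y) <- c("tsne1", "tsne2")
    Y
  })
}
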