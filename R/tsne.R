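## Exact t-SNE from a precomputed dissimilarity matrix. O(n^2) per
## iteration, which is ample at the few-thousand-sample scale this stage
## operates on.

## Gaussian input affinities at a fixed perplexity via per-point binary
## search on the precision beta (squared dissimilarities in the kernel).
tsne_input_p <- function(D2, perplexity, tol = 1e-5, max_iter = 60) {
  n <- nrow(D2)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1
    bmin <- -Inf; bmax <- Inf
    di <- D2[i, -i]
    for (it in seq_len(max_iter)) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) { bmin <- beta
        beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2
      } else { bmax <- beta
        beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sum(p)
  }
  P
}

#' t-SNE embedding of a dissimilarity matrix
#'
#' Exact (non-approximated) t-distributed stochastic neighbour embedding to
#' 2D with random initialisation, early exaggeration, momentum and adaptive
#' gains -- the reference gradient-descent scheme.
#'
#' @param D symmetric dissimilarity matrix (zero diagonal).
#' @param perplexity Gaussian-kernel perplexity (default 100).
#' @param early_exaggeration multiplier on the input affinities during the
#'   first `exaggeration_iter` iterations (default 4).
#' @param n_iter total gradient iterations (default 750).
#' @param eta learning rate (default 200).
#' @param seed integer seed for the random initialisation.
#' @param exaggeration_iter iterations under exaggeration (default 250).
#' @return `n x 2` embedding matrix.
#' @export
tsne_embed <- function(D, perplexity = 100, early_exaggeration = 4,
                       n_iter = 750, eta = 200, seed = 1L,
                       exaggeration_iter = 250) {
  n <- nrow(D)
  if (n <= 3 * perplexity) {
    stop("too few samples for perplexity ", perplexity,
         " (need n > 3 * perplexity); lower the perplexity", call. = FALSE)
  }
  P <- tsne_input_p(D^2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pex <- P * early_exaggeration
  for (it in seq_len(n_iter)) {
    Pit <- if (it <= exaggeration_iter) Pex else P
    momentum <- if (it <= exaggeration_iter) 0.5 else 0.8
    sum_y <- rowSums(Y^2)
    num <- 1 / (1 + outer(sum_y, sum_y, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
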