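#' 2-D feature embedding by t-SNE
#'
#' Exact (non-approximated) t-distributed stochastic neighbour embedding of a
#' feature matrix: per-point Gaussian bandwidths are found by binary search to
#' match the target perplexity, and the Kullback-Leibler divergence between
#' the high-dimensional affinities and the Student-t low-dimensional
#' affinities is minimized by momentum gradient descent with early
#' exaggeration. Quadratic in `n`, intended for the hundreds-of-windows scale
#' of per-subject feature visualization.
#'
#' @param features `n x d` numeric matrix (`n >= 5`).
#' @param perplexity target perplexity (effective neighbour count).
#' @param n_iter gradient-descent iterations.
#' @param seed seed for the initial layout; identical seeds give identical
#'   embeddings.
#' @return `n x 2` coordinate matrix.
#' @export
embed_features <- function(features, perplexity = 15, n_iter = 300, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 5) stopf("need at least 5 points to embed, got %d", n)
  perplexity <- min(perplexity, (n - 1) / 3)

  ## pairwise squared distances
  ss <- rowSums(features^2)
  D2 <- pmax(outer(ss, ss, "+") - 2 * tcrossprod(features), 0)
  diag(D2) <- 0

  ## binary-search precision beta_i so each row's entropy matches perplexity
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) p <- rep(1e-12, length(di)) else p <- p / sump
      h <- -sum(p * log(pmax(p, 1e-12)))
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    momentum <- 0.5
    eta <- 200
    for (it in seq_len(n_iter)) {
      Pit <- if (it <= 50) P * 4 else P       # early exaggeration
      yss <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(yss, yss, "+") - 2 * tcrossprod(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pit - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
      if (it == 50) momentum <- 0.8
    }
    Y
  })
}

#' Scatter plot of an embedding coloured by class label
#'
#' @param coords `n x 2` matrix from [embed_features()].
#' @param labels 0/1 class labels.
#' @param file output PNG path.
#' @param title plot title.
#' @return `file`, invisibly.
#' @export
plot_embedding <- function(coords, labels, file, title = "feature embedding") {
  grDevices::png(file, width = 800, height = 700)
  on.exit(grDevices::dev.off())
  cols <- ifelse(labels == 1, "#d62728", "#2ca02c")
  plot(coords[, 1], coords[, 2], col = cols, pch = 19, cex = 0.8,
       xlab = "dimension 1", ylab = "dimension 2", main = title)
  graphics::legend("topright", legend = c("high", "low"), col = c("#d62728", "#2ca02c"),
                   pch = 19, bty = "n")
  invisible(file)
}
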