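# Compact exact t-SNE (O(n^2)), sufficient for campaign-sized inputs
# (hundreds to a few thousand molecules).  Standard formulation:
# perplexity-calibrated Gaussian input affinities, Student-t output
# kernel, gradient descent with momentum and early exaggeration.

.tsne_perplexity_probs <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1
    betamin <- -Inf; betamax <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP < 1e-300) sumP <- 1e-300
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sumP
  }
  P
}

.tsne_exact <- function(X, perplexity = 30, seed = 1L, maxIter = 350L,
                        eta = 100) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) return(matrix(0, n, 2))
  D2 <- as.matrix(stats::dist(X))^2
  P <- .tsne_perplexity_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  momentum <- 0.5
  Pex <- P * 4  # early exaggeration
  for (it in seq_len(maxIter)) {
    Puse <- if (it <= 100) Pex else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
    if (it == 150) momentum <- 0.8
  }
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}
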