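# internal numerics shared across modules

.rowVars <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowMeans(m)
  (Matrix::rowSums(m^2) - n * mu^2) / (n - 1)
}

# PCA scores of a cells x features matrix via eigen-decomposition of the
# feature covariance (features are assumed <= a few thousand)
.pcaScores <- function(x, n_pcs) {
  x <- as.matrix(x)
  x <- sweep(x, 2, colMeans(x), "-")
  cv <- crossprod(x) / max(nrow(x) - 1, 1)
  ev <- eigen(cv, symmetric = TRUE)
  k <- min(n_pcs, ncol(x), nrow(x))
  scores <- x %*% ev$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

# k nearest neighbours by Euclidean distance, blocked to bound memory;
# returns an n x k matrix of row indices
.knnIndices <- function(coords, k, exclude_self = TRUE, block = 1024L) {
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of points")
  sq <- rowSums(coords^2)
  out <- matrix(0L, nrow = n, ncol = k)
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(coords[s:e, , drop = FALSE],
                                                   coords)
    if (exclude_self)
      d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    for (i in seq_len(e - s + 1L))
      out[s + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
  }
  out
}

.l2normRows <- function(x) {
  nr <- sqrt(rowSums(x^2))
  nr[nr == 0] <- 1
  x / nr
}
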