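# Independent brute-force oracles and tiny fixtures used across test files.

# Well-separated Gaussian blobs in 2D; returns matrix + labels.
make_blobs <- function(n_per = 10, k = 3, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- cbind(sep * cos(2 * pi * seq_len(k) / k),
                   sep * sin(2 * pi * seq_len(k) / k))
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(rnorm(n_per, centers[j, 1]), rnorm(n_per, centers[j, 2]))
  }))
  rownames(x) <- sprintf("i%02d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Jaccard network by explicit set operations (double loop).
oracle_jaccard <- function(ic) {
  k <- ncol(ic)
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- which(ic[, i] == 1)
      b <- which(ic[, j] == 1)
      out[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  out
}

# Kernel similarity by explicit pairwise evaluation.
oracle_kernel <- function(walked, sigma = 1) {
  k <- ncol(walked)
  out <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- exp(-sum((walked[, i] - walked[, j])^2) / (2 * sigma^2))
    }
  }
  out
}

# Random walk with restart fixed point by direct linear solve:
# F = (1 - alpha) * F0 * (I - alpha * A_hat)^(-1).
oracle_rwr <- function(f0, adjacency, alpha, normalize = TRUE) {
  a <- adjacency
  if (normalize) a <- a / rowSums(a)
  (1 - alpha) * f0 %*% solve(diag(ncol(f0)) - alpha * a)
}

# Mean silhouette by a per-instance double loop.
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Connected components by union-find on a nonnegative weight matrix.
oracle_components <- function(w, tol = 0) {
  n <- nrow(w)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (w[i, j] > tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# Ensemble of identical clusterings (degenerate case).
identical_ensemble <- function(labels, m = 5) {
  as_ensemble(matrix(rep(labels, m), ncol = m))
}
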