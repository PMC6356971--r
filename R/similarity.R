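#' Jaccard cluster-cluster network
#'
#' Edge (x, y) is the Jaccard index of the two clusters' instance sets,
#' `|Lx intersect Ly| / |Lx union Ly|`. Clusters from the same base
#' clustering are disjoint, so within-clustering off-diagonal entries are 0;
#' the diagonal is 1 (a set against itself) unless `self_loop = FALSE`.
#'
#' @param ic Binary instance-cluster matrix from [pool_to_ic()].
#' @param self_loop Keep the unit diagonal (default) or zero it.
#' @return A symmetric K_total x K_total matrix with entries in `[0, 1]`.
#' @examples
#' ic <- pool_to_ic(as_ensemble(cbind(c(1, 1, 2, 2), c(1, 2, 2, 2))))
#' jaccard_network(ic)
#' @export
jaccard_network <- function(ic, self_loop = TRUE) {
  sizes <- colSums(ic)
  if (any(sizes == 0)) {
    stop("empty cluster column(s): ", paste(which(sizes == 0), collapse = ", "),
         " (Jaccard 0/0 undefined)", call. = FALSE)
  }
  inter <- crossprod(ic)             # |Lx intersect Ly|
  union <- outer(sizes, sizes, "+") - inter
  j <- inter / union
  diag(j) <- if (isTRUE(self_loop)) 1 else 0
  unname(j)
}

#' Random walk with restart on the cluster network
#'
#' Iterates `F <- alpha * F %*% A_hat + (1 - alpha) * F0` from `F0 = ic`
#' until the maximum absolute entrywise change drops below `tol`. By default
#' the adjacency is row-normalized to a stochastic transition matrix, which
#' guarantees convergence for `alpha < 1`; `normalize = FALSE` iterates on
#' the raw adjacency (may diverge when `alpha * ||A|| >= 1`).
#'
#' @param ic Binary instance-cluster matrix (the walk's restart state F0).
#' @param adjacency Symmetric nonnegative K_total x K_total cluster network,
#'   typically from [jaccard_network()].
#' @param alpha Retention probability in `[0, 1)`; `1 - alpha` is the
#'   restart probability.
#' @param tol Convergence tolerance (max absolute entry change).
#' @param max_iter Iteration cap.
#' @param normalize Row-normalize the adjacency before walking.
#' @return The converged n x K_total matrix with attributes `iterations`
#'   and `residual`.
#' @export
random_walk_restart <- function(ic, adjacency, alpha = 0.9, tol = 1e-6,
                                max_iter = 1000, normalize = TRUE) {
  if (alpha < 0 || alpha >= 1) stop("alpha must lie in [0, 1)", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  f0 <- unname(ic[, , drop = FALSE]) * 1
  if (ncol(f0) != nrow(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square with one row per ic column", call. = FALSE)
  }
  a <- adjacency
  if (isTRUE(normalize)) {
    d <- rowSums(a)
    if (any(d <= 0)) stop("adjacency has a zero-degree row; cannot normalize", call. = FALSE)
    a <- a / d
  }
  if (alpha == 0) {
    out <- f0
    attr(out, "iterations") <- 1L
    attr(out, "residual") <- 0
    return(restore_ic_attrs(out, ic))
  }
  f <- f0
  restart <- (1 - alpha) * f0
  for (it in seq_len(max_iter)) {
    f_new <- alpha * (f %*% a) + restart
    resid <- max(abs(f_new - f))
    f <- f_new
    if (!is.finite(resid)) {
      stop("random walk diverged (non-finite residual at iteration ", it,
           "); consider normalize = TRUE", call. = FALSE)
    }
    if (resid < tol) {
      attr(f, "iterations") <- it
      attr(f, "residual") <- resid
      return(restore_ic_attrs(f, ic))
    }
  }
  stop(sprintf("random walk did not converge in %d iterations (residual %.3g > tol %.3g)",
               max_iter, resid, tol), call. = FALSE)
}

restore_ic_attrs <- function(x, ic) {
  dimnames(x) <- dimnames(ic)
  attr(x, "blocks") <- attr(ic, "blocks")
  attr(x, "instance_ids") <- attr(ic, "instance_ids")
  x
}

#' Scaled exponential similarity between walked cluster profiles
#'
#' `sim(i, j) = exp(-d2(zi, zj) / (2 sigma^2))` where `zi`, `zj` are columns
#' of the converged walk matrix and `d2` is squared Euclidean distance.
#'
#' @param walked n x K_total matrix from [random_walk_restart()].
#' @param sigma Kernel bandwidth (> 0); the method's default is 1.
#' @return A symmetric K_total x K_total matrix with unit diagonal and
#'   entries in `(0, 1]`.
#' @export
kernel_similarity <- function(walked, sigma = 1) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  d2 <- as.matrix(stats::dist(t(walked)))^2
  s <- exp(-d2 / (2 * sigma^2))
  diag(s) <- 1
  unname(s)
}
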