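#' Bipartite instance-cluster graph
#'
#' Assembles the weighted bipartite graph whose two vertex sets are the
#' instances and the pooled base clusters; the only edges connect an
#' instance to a cluster, with weight equal to the refined association.
#' In block form `W = rbind(cbind(0, RIC), cbind(t(RIC), 0))` with instance
#' vertices first.
#'
#' @param ric Refined association matrix from [build_ric()] (a binary IC
#'   matrix also works).
#' @return A symmetric (n + K_total) square matrix with attributes
#'   `n_instances` and `instance_ids`. Isolated cluster vertices (all-zero
#'   columns) are dropped with a warning; an isolated instance (all-zero
#'   row) is an error since it cannot be placed in any partition.
#' @export
build_bipartite <- function(ric) {
  ids <- attr(ric, "instance_ids") %||% rownames(ric) %||% as.character(seq_len(nrow(ric)))
  zero_rows <- which(rowSums(ric) == 0)
  if (length(zero_rows) > 0) {
    stop("instance(s) with all-zero association: ",
         paste(ids[zero_rows], collapse = ", "), call. = FALSE)
  }
  zero_cols <- which(colSums(ric) == 0)
  if (length(zero_cols) > 0) {
    warning("dropping ", length(zero_cols), " isolated cluster vertex(es)")
    ric <- ric[, -zero_cols, drop = FALSE]
  }
  n <- nrow(ric)
  k <- ncol(ric)
  w <- rbind(
    cbind(matrix(0, n, n), unname(ric)),
    cbind(t(unname(ric)), matrix(0, k, k))
  )
  attr(w, "n_instances") <- n
  attr(w, "instance_ids") <- ids
  w
}

#' Normalized-cut spectral partition of a (bipartite) graph
#'
#' Computes the symmetric normalized Laplacian
#' `L_sym = I - D^(-1/2) W D^(-1/2)`, takes the eigenvectors of its k
#' smallest eigenvalues, row-normalizes the embedding, and clusters the rows
#' with k-means (20 restarts). With `k = "auto"`, k is chosen by the
#' eigengap heuristic: the i (searched over `2..eigengap_max`) maximizing
#' `lambda[i+1] - lambda[i]`, smallest i on ties (prefer fewer clusters).
#' Only instance-vertex labels are returned; cluster vertices are clustered
#' alongside but discarded.
#'
#' @param graph Symmetric nonnegative weight matrix, typically from
#'   [build_bipartite()] (its `n_instances` attribute restricts the output;
#'   absent that, all vertices are treated as instances).
#' @param k Number of partitions (>= 2) or `"auto"`.
#' @param seed Seed for the embedding k-means.
#' @param eigengap_max Upper end of the eigengap search range (capped at the
#'   number of vertices minus 1).
#' @param nstart k-means restarts on the embedding.
#' @return An `rwce_spectral` object: `labels` (instance labels, contiguous
#'   by first appearance), `chosen_k`, `eigenvalues` (ascending), `k_auto`,
#'   `instance_ids`.
#' @export
spectral_partition <- function(graph, k = "auto", seed = 1,
                               eigengap_max = 15, nstart = 20) {
  w <- unname(as.matrix(graph))
  nv <- nrow(w)
  n_inst <- attr(graph, "n_instances") %||% nv
  ids <- attr(graph, "instance_ids") %||% as.character(seq_len(n_inst))
  deg <- rowSums(w)
  if (any(deg <= 0)) stop("graph has zero-degree vertex(es)", call. = FALSE)

  inv_sqrt <- 1 / sqrt(deg)
  l_sym <- -w * outer(inv_sqrt, inv_sqrt)
  diag(l_sym) <- diag(l_sym) + 1
  l_sym <- (l_sym + t(l_sym)) / 2            # enforce exact symmetry
  eig <- eigen(l_sym, symmetric = TRUE)
  lambda <- pmax(rev(eig$values), 0)          # ascending; clip tiny negatives
  vectors <- eig$vectors[, rev(seq_len(nv)), drop = FALSE]

  k_auto <- identical(k, "auto")
  if (k_auto) {
    k <- eigengap_k(lambda, eigengap_max)
  } else {
    k <- as.integer(k)
    if (k < 2) stop("k must be >= 2", call. = FALSE)
    n_comp <- sum(lambda < 1e-10)
    if (n_comp > k) {
      warning("graph has ", n_comp, " connected components but k = ", k,
              "; labels will follow components")
    }
  }
  u <- vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(u^2))
  nz <- norms > 0
  if (!all(nz)) warning(sum(!nz), " zero row(s) in the spectral embedding left unnormalized")
  u[nz, ] <- u[nz, , drop = FALSE] / norms[nz]

  fit <- with_rng(seed, run_kmeans(u, k, nstart = nstart, iter_max = 100))
  labels <- relabel_contiguous(fit[seq_len(n_inst)])

  structure(
    list(labels = labels, chosen_k = as.integer(k),
         eigenvalues = lambda, k_auto = k_auto, instance_ids = ids),
    class = "rwce_spectral"
  )
}

# Eigengap choice of k on an ascending spectrum: argmax_{i >= 2} of
# lambda[i+1] - lambda[i], smallest i on (near-)ties. The search is capped
# at half the spectrum: a bipartite graph's normalized-Laplacian spectrum is
# symmetric about 1, so every low-end gap reappears mirrored at the top and
# the upper half carries no extra model-selection information.
eigengap_k <- function(lambda, eigengap_max = 15) {
  q_max <- min(eigengap_max, floor(length(lambda) / 2))
  if (q_max < 2) return(2L)
  idx <- 2:q_max
  gaps <- lambda[idx + 1L] - lambda[idx]
  as.integer(idx[which(gaps >= max(gaps) - 1e-9)[1]])
}

#' @export
print.rwce_spectral <- function(x, ...) {
  cat(sprintf("<rwce_spectral> %d instances in %d clusters (k %s)\n",
              length(x$labels), x$chosen_k,
              if (x$k_auto) "by eigengap" else "fixed"))
  invisible(x)
}
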