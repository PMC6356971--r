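#' Generate an ensemble of base k-means clusterings
#'
#' Runs k-means `ensemble_size` times on one view, each run with a cluster
#' count K drawn uniformly from `[k_min, k_max]`. Each run uses k-means++
#' seeding with 10 restarts (best total within-cluster sum of squares kept).
#' The whole ensemble is a deterministic function of the data and the seed.
#'
#' @param data A data frame (first column `instance_id`, or any non-numeric
#'   first column treated as ids) or numeric matrix: instances x features.
#' @param ensemble_size Number of base clusterings (M), at least 2.
#' @param k_min Smallest K to draw (>= 2).
#' @param k_max Largest K; `NULL` sets it from `k_range_mode`.
#' @param k_range_mode `"sqrt"` caps K at `ceiling(sqrt(n))` (sensible:
#'   K near n degenerates to singletons), `"linear"` at `n - 1`.
#' @param scale_features Z-score features first (constant features are left
#'   unscaled).
#' @param seed Integer seed.
#' @param view_name Label carried through to results.
#' @return An `rwce_ensemble`: list with `labels` (n x M integer matrix, each
#'   column a crisp clustering with contiguous labels `1..K_m`), `ks`,
#'   `instance_ids`, `view_name`.
#' @examples
#' sim <- simulate_multiview(n = 40, k = 2, views = 1, features = 5, seed = 1)
#' ens <- generate_base_clusterings(sim$views[[1]], ensemble_size = 5, seed = 1)
#' ens$ks
#' @export
generate_base_clusterings <- function(data, ensemble_size = 50,
                                      k_min = 2, k_max = NULL,
                                      k_range_mode = c("sqrt", "linear"),
                                      scale_features = TRUE,
                                      seed = 1, view_name = "view") {
  k_range_mode <- match.arg(k_range_mode)
  v <- as_view_matrix(data)
  n <- nrow(v$x)
  if (ensemble_size < 2) stop("ensemble_size must be >= 2", call. = FALSE)
  if (is.null(k_max)) {
    k_max <- if (k_range_mode == "sqrt") ceiling(sqrt(n)) else n - 1L
    k_max <- max(k_max, k_min)
  }
  if (k_min < 2 || k_max < k_min || k_max > n - 1) {
    stop("need 2 <= k_min <= k_max <= n - 1", call. = FALSE)
  }
  x <- v$x
  if (isTRUE(scale_features)) {
    sds <- apply(x, 2, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    x <- scale(x, center = TRUE, scale = sds)
  }

  labels <- matrix(NA_integer_, n, ensemble_size)
  ks <- integer(ensemble_size)
  for (j in seq_len(ensemble_size)) {
    res <- with_rng(derive_seed(seed, j), {
      k_j <- sample.int(k_max - k_min + 1L, 1L) + k_min - 1L
      list(k = k_j, labels = run_kmeans(x, k_j))
    })
    lab <- relabel_contiguous(res$labels)
    labels[, j] <- lab
    ks[j] <- max(lab)
  }
  new_ensemble(labels, v$ids, view_name)
}

# k-means with k-means++ seeding and `nstart` restarts; returns labels.
# Falls back to Lloyd when Hartigan-Wong rejects an initialization.
run_kmeans <- function(x, k, nstart = 10, iter_max = 300) {
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- kmeanspp_centers(x, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max)),
      error = function(e) {
        suppressWarnings(stats::kmeans(x, centers = centers, iter.max = iter_max,
                                       algorithm = "Lloyd"))
      }
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best$cluster
}

# k-means++ seeding: first center uniform, each next with probability
# proportional to the squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      cand <- setdiff(seq_len(n), idx[seq_len(j)])
      idx[j + 1L] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j + 1L], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE] + stats::runif(k * ncol(x), -1e-9, 1e-9) # break exact duplicates
}

new_ensemble <- function(labels, instance_ids, view_name = "view") {
  stopifnot(is.matrix(labels), nrow(labels) == length(instance_ids))
  ks <- apply(labels, 2, max)
  for (j in seq_len(ncol(labels))) {
    if (!setequal(unique(labels[, j]), seq_len(ks[j]))) {
      stop("clustering ", j, " is not a crisp labelling 1..K", call. = FALSE)
    }
  }
  structure(
    list(labels = labels, ks = as.integer(ks),
         instance_ids = instance_ids, view_name = view_name),
    class = "rwce_ensemble"
  )
}

#' Assemble an ensemble from precomputed clusterings
#'
#' Accepts a data frame with an `instance_id` column (or non-numeric first
#' column) and one integer label column per clustering, a plain label
#' matrix, or a list of label vectors. Labels are relabelled to contiguous
#' `1..K` per clustering.
#'
#' @param x Clusterings in one of the forms above.
#' @param view_name Label carried through to results.
#' @return An `rwce_ensemble`.
#' @export
as_ensemble <- function(x, view_name = "view") {
  if (inherits(x, "rwce_ensemble")) return(x)
  ids <- NULL
  if (is.data.frame(x)) {
    id_col <- which(names(x) == "instance_id")
    if (length(id_col) == 0 && !is.numeric(x[[1]])) id_col <- 1L
    if (length(id_col) > 0) {
      ids <- as.character(x[[id_col[1]]])
      x <- x[-id_col[1]]
    }
    x <- as.matrix(x)
  } else if (is.list(x) && !is.matrix(x)) {
    x <- do.call(cbind, lapply(x, as.integer))
  }
  if (!is.matrix(x) || ncol(x) < 2) {
    stop("an ensemble needs at least 2 clusterings", call. = FALSE)
  }
  if (is.null(ids)) ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  labels <- apply(x, 2, function(col) relabel_contiguous(check_labels(col)))
  new_ensemble(labels, ids, view_name)
}

#' @export
print.rwce_ensemble <- function(x, ...) {
  cat(sprintf("<rwce_ensemble> '%s': %d instances, %d clusterings, K in [%d, %d]\n",
              x$view_name, nrow(x$labels), ncol(x$labels), min(x$ks), max(x$ks)))
  invisible(x)
}

#' Pool an ensemble into the binary instance-cluster matrix
#'
#' Column `j` of the result is the 0/1 indicator of one base cluster;
#' columns are ordered by clustering, then by within-clustering cluster id.
#' Every row sums to the ensemble size M (each instance sits in exactly one
#' cluster per clustering).
#'
#' @param ensemble An `rwce_ensemble`.
#' @return An n x K_total binary matrix with attributes `blocks` (list of
#'   column indices per clustering) and `instance_ids`; column names
#'   `m<clustering>_c<cluster>`.
#' @examples
#' ens <- as_ensemble(cbind(c(1, 1, 2, 2), c(1, 2, 2, 2)))
#' pool_to_ic(ens)
#' @export
pool_to_ic <- function(ensemble) {
  ensemble <- as_ensemble(ensemble)
  n <- nrow(ensemble$labels)
  k_total <- sum(ensemble$ks)
  ic <- matrix(0L, n, k_total)
  blocks <- vector("list", length(ensemble$ks))
  off <- 0L
  for (j in seq_along(ensemble$ks)) {
    k_j <- ensemble$ks[j]
    blocks[[j]] <- off + seq_len(k_j)
    ic[cbind(seq_len(n), off + ensemble$labels[, j])] <- 1L
    off <- off + k_j
  }
  colnames(ic) <- unlist(lapply(seq_along(ensemble$ks), function(j) {
    sprintf("m%d_c%d", j, seq_len(ensemble$ks[j]))
  }))
  rownames(ic) <- ensemble$instance_ids
  attr(ic, "blocks") <- blocks
  attr(ic, "instance_ids") <- ensemble$instance_ids
  ic
}
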