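#' Pipeline configuration
#'
#' Bundles every tunable of the random-walk cluster-ensemble pipeline.
#' Defaults follow the method's published settings where stated
#' (`sigma = 1`, `dc = 1`, `tol = 1e-6`) and standard choices elsewhere.
#'
#' @param ensemble_size Number of base clusterings per view (M). Default 50.
#' @param alpha Random-walk retention probability in `[0, 1)`; `1 - alpha`
#'   is the restart probability. Default 0.9.
#' @param sigma Bandwidth of the scaled exponential similarity kernel (> 0).
#' @param dc Decay mass distributed over non-member clusters when refining
#'   the instance-cluster matrix (> 0). Default 1.
#' @param tol Convergence tolerance for the random walk (max absolute
#'   entrywise change between iterations).
#' @param max_iter Iteration cap for the random walk.
#' @param k Number of consensus clusters, or `"auto"` for eigengap selection.
#' @param k_range_mode How the per-clustering cluster count K is drawn for
#'   base clusterings: `"sqrt"` draws from `[k_min, ceiling(sqrt(n))]`,
#'   `"linear"` from `[k_min, n - 1]`.
#' @param k_min Smallest base-clustering K. Default 2.
#' @param k_max Largest base-clustering K; `NULL` means set from
#'   `k_range_mode` and the view size.
#' @param scale_features Z-score each feature before k-means. Default `TRUE`
#'   (k-means is scale-sensitive; expression-like views mix units).
#' @param normalize_adjacency Row-normalize the Jaccard network to a
#'   stochastic transition matrix before the walk (guarantees convergence
#'   for `alpha < 1`). `FALSE` iterates on the raw adjacency.
#' @param eigengap_max Upper bound of the eigengap search range for
#'   `k = "auto"`. Default 15.
#' @param seed Master seed; every stochastic stage derives its own stream
#'   from it via [derive_seed()].
#' @return An object of class `rwce_config` (a validated named list).
#' @examples
#' cfg <- rwce_config(ensemble_size = 20, seed = 42)
#' cfg$alpha
#' @export
rwce_config <- function(ensemble_size = 50,
                        alpha = 0.9,
                        sigma = 1,
                        dc = 1,
                        tol = 1e-6,
                        max_iter = 1000,
                        k = "auto",
                        k_range_mode = c("sqrt", "linear"),
                        k_min = 2,
                        k_max = NULL,
                        scale_features = TRUE,
                        normalize_adjacency = TRUE,
                        eigengap_max = 15,
                        seed = 1) {
  k_range_mode <- match.arg(k_range_mode)
  if (!is.numeric(ensemble_size) || ensemble_size < 2) {
    stop("ensemble_size must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("alpha must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!is.numeric(dc) || dc <= 0) stop("dc must be > 0", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (!identical(k, "auto")) {
    if (!is.numeric(k) || k < 2) stop("k must be 'auto' or an integer >= 2", call. = FALSE)
    k <- as.integer(k)
  }
  if (!is.numeric(k_min) || k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  if (!is.null(k_max) && k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  structure(
    list(
      ensemble_size = as.integer(ensemble_size), alpha = alpha, sigma = sigma,
      dc = dc, tol = tol, max_iter = as.integer(max_iter), k = k,
      k_range_mode = k_range_mode, k_min = as.integer(k_min),
      k_max = if (is.null(k_max)) NULL else as.integer(k_max),
      scale_features = isTRUE(scale_features),
      normalize_adjacency = isTRUE(normalize_adjacency),
      eigengap_max = as.integer(eigengap_max), seed = as.integer(seed)
    ),
    class = "rwce_config"
  )
}

#' @export
print.rwce_config <- function(x, ...) {
  cat("<rwce_config>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm, if (is.null(val)) "auto (from data)" else format(val)))
  }
  invisible(x)
}

#' Build a configuration from a named list (e.g. parsed YAML)
#'
#' Unknown fields are rejected so config-file typos surface early.
#'
#' @param x Named list of configuration fields.
#' @return An `rwce_config`.
#' @export
as_rwce_config <- function(x) {
  stopifnot(is.list(x))
  known <- names(formals(rwce_config))
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    stop("unknown configuration fields: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(rwce_config, x)
}
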