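#' Refine a cluster ensemble into a consensus clustering
#'
#' The core refinement: pool the ensemble into the binary instance-cluster
#' matrix, build the Jaccard cluster network, diffuse it by random walk with
#' restart, convert walked cluster profiles to similarities with the scaled
#' exponential kernel, fill the refined association matrix, and partition
#' the resulting bipartite instance-cluster graph by normalized-cut spectral
#' clustering (eigengap selection of k unless fixed in the config).
#'
#' @param ensemble An `rwce_ensemble` (or anything [as_ensemble()] accepts).
#' @param config An [rwce_config()].
#' @param source Name recorded on the result.
#' @return An `rwce_consensus`: `labels`, `chosen_k`, `source`,
#'   `instance_ids`, the underlying `spectral` fit, and diagnostics
#'   (`rwr_iterations`, `rwr_residual`).
#' @examples
#' ens <- as_ensemble(cbind(rep(1:2, each = 10), rep(1:2, each = 10)))
#' fit <- rwce_refine(ens, rwce_config(seed = 1))
#' fit$chosen_k
#' @export
rwce_refine <- function(ensemble, config = rwce_config(), source = NULL) {
  ensemble <- as_ensemble(ensemble)
  stopifnot(inherits(config, "rwce_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  ic <- stage("pool_to_ic", pool_to_ic(ensemble))
  adj <- stage("jaccard_network", jaccard_network(ic))
  walked <- stage("random_walk_restart",
                  random_walk_restart(ic, adj, alpha = config$alpha,
                                      tol = config$tol, max_iter = config$max_iter,
                                      normalize = config$normalize_adjacency))
  sim <- stage("kernel_similarity", kernel_similarity(walked, sigma = config$sigma))
  ric <- stage("build_ric", build_ric(ic, sim, dc = config$dc))
  graph <- stage("build_bipartite", build_bipartite(ric))
  spec <- stage("spectral_partition",
                spectral_partition(graph, k = config$k,
                                   seed = derive_seed(config$seed, 33),
                                   eigengap_max = config$eigengap_max))
  structure(
    list(labels = spec$labels, chosen_k = spec$chosen_k,
         source = source %||% ensemble$view_name,
         instance_ids = ensemble$instance_ids, spectral = spec,
         rwr_iterations = attr(walked, "iterations"),
         rwr_residual = attr(walked, "residual"),
         config = config),
    class = "rwce_consensus"
  )
}

#' Consensus clustering of a single data view
#'
#' Generates the base k-means ensemble for one view and refines it.
#'
#' @param data Instances x features data frame (first column `instance_id`)
#'   or numeric matrix.
#' @param config An [rwce_config()].
#' @param view_name Name recorded on the result.
#' @return An `rwce_consensus`.
#' @export
run_single_view <- function(data, config = rwce_config(), view_name = "view") {
  ensemble <- generate_base_clusterings(
    data,
    ensemble_size = config$ensemble_size,
    k_min = config$k_min, k_max = config$k_max,
    k_range_mode = config$k_range_mode,
    scale_features = config$scale_features,
    seed = config$seed, view_name = view_name
  )
  rwce_refine(ensemble, config, source = view_name)
}

#' Integrate multiple data views into one consensus subtyping
#'
#' Stage 1-2: each view is clustered independently (base ensemble +
#' refinement) under a view-specific sub-seed derived from the master seed,
#' so per-view results do not depend on view order. Stage 3: the per-view
#' consensus clusterings form a new T-member ensemble, refined once more
#' into the cross-view consensus.
#'
#' @param views Named list of data frames/matrices with identical
#'   `instance_id` sets in identical order.
#' @param config An [rwce_config()]. The same parameters are used at both
#'   stages.
#' @return An `rwce_consensus` with `source = "integration"`; per-view fits
#'   are kept in `$views`.
#' @examples
#' sim <- simulate_multiview(n = 60, k = 2, views = 2, features = 10,
#'                           separation = 8, seed = 3)
#' fit <- run_integration(sim$views, rwce_config(ensemble_size = 10, seed = 3))
#' fit$chosen_k
#' @export
run_integration <- function(views, config = rwce_config()) {
  if (!is.list(views) || length(views) < 2) {
    stop("integration needs at least 2 views", call. = FALSE)
  }
  if (is.null(names(views)) || any(names(views) == "")) {
    names(views) <- paste0("view", seq_along(views))
  }
  mats <- lapply(names(views), function(nm) as_view_matrix(views[[nm]], arg = nm))
  ref_ids <- mats[[1]]$ids
  for (t in seq_along(mats)[-1]) {
    if (!identical(mats[[t]]$ids, ref_ids)) {
      stop("view '", names(views)[t], "' has instance ids not aligned with '",
           names(views)[1], "'", call. = FALSE)
    }
  }
  # sub-seeds derive from view names, so per-view results are invariant to
  # the order the views are listed in
  per_view <- purrr::imap(views, function(view, nm) {
    cfg_t <- config
    cfg_t$seed <- derive_seed(config$seed, 1000 + string_stream(nm))
    run_single_view(view, cfg_t, view_name = nm)
  })

  stage2 <- new_ensemble(
    do.call(cbind, lapply(per_view, function(f) relabel_contiguous(f$labels))),
    ref_ids, view_name = "integration"
  )
  cfg_2 <- config
  cfg_2$seed <- derive_seed(config$seed, 2000)
  out <- rwce_refine(stage2, cfg_2, source = "integration")
  out$views <- per_view
  out
}

#' Read a delimited numeric view
#'
#' Reads a CSV (or TSV, by extension or `sep`) whose first column is the
#' instance id and whose header row names the features.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` infers `"\t"` for `.tsv`/`.txt`, `","`
#'   otherwise.
#' @return A tibble with `instance_id` followed by numeric feature columns.
#' @export
read_view <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- "instance_id"
  df$instance_id <- as.character(df$instance_id)
  v <- as_view_matrix(df, arg = path)       # validates numeric, no NA
  tibble::as_tibble(df)
}

#' Write consensus labels as TSV
#'
#' @param fit An `rwce_consensus` or `rwce_spectral`.
#' @param path Output path; columns `instance_id`, `label`.
#' @return `path`, invisibly.
#' @export
write_labels <- function(fit, path) {
  utils::write.table(tidy(fit), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.rwce_consensus <- function(x, ...) {
  cat(sprintf("<rwce_consensus> '%s': %d instances in %d clusters\n",
              x$source, length(x$labels), x$chosen_k))
  cat(sprintf("  random walk: %d iterations, residual %.2e\n",
              x$rwr_iterations, x$rwr_residual))
  if (!is.null(x$views)) {
    cat("  integrated views:", paste(names(x$views), collapse = ", "), "\n")
  }
  invisible(x)
}
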