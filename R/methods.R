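# Broom-style accessors and plots for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @describeIn rwce_refine One row per instance: `instance_id`, `label`.
#' @param x An `rwce_consensus`.
#' @param ... Unused.
#' @export
tidy.rwce_consensus <- function(x, ...) {
  tibble::tibble(instance_id = x$instance_ids, label = x$labels)
}

#' @describeIn rwce_refine One-row model summary: source, n, chosen k,
#'   whether k was selected by eigengap, leading eigengap, random-walk
#'   iteration count and residual.
#' @export
glance.rwce_consensus <- function(x, ...) {
  lam <- x$spectral$eigenvalues
  kk <- x$chosen_k
  tibble::tibble(
    source = x$source,
    n = length(x$labels),
    chosen_k = kk,
    k_auto = x$spectral$k_auto,
    eigengap = if (kk + 1 <= length(lam)) lam[kk + 1] - lam[kk] else NA_real_,
    rwr_iterations = x$rwr_iterations,
    rwr_residual = x$rwr_residual
  )
}

#' @export
tidy.rwce_spectral <- function(x, ...) {
  tibble::tibble(instance_id = x$instance_ids, label = x$labels)
}

#' @export
glance.rwce_spectral <- function(x, ...) {
  tibble::tibble(
    n = length(x$labels), chosen_k = x$chosen_k, k_auto = x$k_auto,
    lambda_k = x$eigenvalues[x$chosen_k],
    lambda_k1 = x$eigenvalues[x$chosen_k + 1]
  )
}

#' Eigenvalue spectrum with the eigengap choice highlighted
#'
#' @param object An `rwce_spectral` or `rwce_consensus`.
#' @param n_eigenvalues How many leading eigenvalues to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rwce_spectral <- function(object, n_eigenvalues = 15, ...) {
  q <- min(n_eigenvalues, length(object$eigenvalues))
  df <- tibble::tibble(index = seq_len(q), lambda = object$eigenvalues[seq_len(q)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$lambda)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k + 0.5, linetype = "dashed") +
    ggplot2::labs(
      x = "eigenvalue index (ascending)",
      y = expression(lambda[i]),
      title = sprintf("Normalized-Laplacian spectrum (k = %d%s)",
                      object$chosen_k, if (object$k_auto) ", eigengap" else "")
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rwce_consensus <- function(object, n_eigenvalues = 15, ...) {
  autoplot(object$spectral, n_eigenvalues = n_eigenvalues, ...)
}

#' Cluster sizes of a consensus fit
#'
#' @param fit An `rwce_consensus`.
#' @return A ggplot bar chart of per-cluster instance counts.
#' @export
plot_cluster_sizes <- function(fit) {
  df <- tidy(fit) |> dplyr::count(.data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$label), y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "consensus cluster", y = "instances",
                  title = sprintf("Consensus clusters ('%s')", fit$source)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
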