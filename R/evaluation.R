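#' Mean silhouette width of a clustering
#'
#' For each instance, `s = (b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own cluster's other members and `b` the smallest mean
#' distance to another cluster; members of singleton clusters score 0 (the
#' usual convention). Returns the mean over instances.
#'
#' @param data Instances x features data frame or matrix (same input form as
#'   the clustering functions).
#' @param labels Integer cluster labels, length n.
#' @return A single number in `[-1, 1]`.
#' @export
silhouette_mean <- function(data, labels) {
  v <- as_view_matrix(data)
  labels <- check_labels(labels, n = nrow(v$x))
  k <- length(unique(labels))
  if (k < 2) stop("silhouette needs at least 2 clusters", call. = FALSE)
  d <- as.matrix(stats::dist(v$x))
  groups <- split(seq_len(nrow(d)), labels)
  sizes <- lengths(groups)
  # mean distance from every instance to each cluster
  mean_to <- vapply(groups, function(g) rowSums(d[, g, drop = FALSE]) / length(g),
                    numeric(nrow(d)))
  s <- numeric(nrow(d))
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (sizes[gi] == 1) { s[g] <- 0; next }
    a <- mean_to[g, gi] * sizes[gi] / (sizes[gi] - 1)   # exclude self (d = 0)
    b <- apply(mean_to[g, -gi, drop = FALSE], 1, min)
    denom <- pmax(a, b)
    s[g] <- ifelse(denom > 0, (b - a) / denom, 0)
  }
  mean(s)
}

#' Log-rank test for survival differences between clusters
#'
#' Classical log-rank chi-squared test (k - 1 degrees of freedom for k
#' groups) comparing survival distributions across cluster labels.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param labels Group labels (>= 2 groups, each with at least one subject).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, labels) {
  stopifnot(length(time) == length(event), length(time) == length(labels))
  g <- factor(labels)
  if (nlevels(g) < 2) stop("log-rank needs at least 2 groups", call. = FALSE)
  if (sum(event) == 0) stop("no events observed; log-rank undefined", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- nlevels(g) - 1L
  tibble::tibble(
    statistic = unname(fit$chisq),
    df = df,
    p_value = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE)
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the contingency-table closed form;
#' 1 for identical partitions (up to label renaming), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A single number (at most 1).
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  a <- check_labels(relabel_contiguous(labels_a), arg = "labels_a")
  b <- check_labels(relabel_contiguous(labels_b), arg = "labels_b")
  if (length(a) != length(b)) stop("label vectors must have equal length", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)      # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Score a clustering against data, truth and survival
#'
#' Convenience wrapper producing one tidy row: mean silhouette on the given
#' view, adjusted Rand index when true labels are supplied, and the
#' log-rank statistic/p-value when survival columns are supplied.
#'
#' @param data Instances x features view used for the silhouette.
#' @param labels Cluster labels to score.
#' @param truth Optional reference labels.
#' @param survival Optional data frame with columns `time` and `event`.
#' @return One-row tibble: `n`, `k`, `silhouette`, `ari`, `logrank_stat`,
#'   `logrank_p` (NA where the input was not supplied).
#' @export
evaluate_clustering <- function(data, labels, truth = NULL, survival = NULL) {
  labels <- check_labels(labels)
  out <- tibble::tibble(
    n = length(labels),
    k = length(unique(labels)),
    silhouette = silhouette_mean(data, labels),
    ari = NA_real_, logrank_stat = NA_real_, logrank_p = NA_real_
  )
  if (!is.null(truth)) out$ari <- adjusted_rand(labels, truth)
  if (!is.null(survival)) {
    lr <- logrank_test(survival$time, survival$event, labels)
    out$logrank_stat <- lr$statistic
    out$logrank_p <- lr$p_value
  }
  out
}
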