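#' Simulate multi-view data with a shared latent partition
#'
#' Draws one Gaussian-mixture matrix per view. All views share the same
#' latent class labels (the premise of multi-omics integration: each data
#' type carries a partly-independent reflection of the same subtypes), but
#' draw independent noise. Within-cluster standard deviation is 1 in every
#' feature, so `separation` is expressed in within-cluster SD units: cluster
#' centers are scaled so the minimum pairwise Euclidean distance between
#' centers (over the signal features) equals `separation`.
#'
#' @param n Number of instances (shared across views).
#' @param k Number of latent clusters.
#' @param proportions Cluster mixing proportions (length `k`, sums to 1).
#'   `NULL` means equal. Class sizes are rounded deterministically
#'   (largest-remainder), so e.g. `c(0.5, 0.5)` with `n = 100` gives 50/50.
#' @param views Number of views, or a list of per-view settings, each a list
#'   with any of `features`, `separation`, `noise_fraction`, `name`.
#' @param features Features per view (used when `views` is a count).
#' @param separation Between-center distance in within-cluster SD units;
#'   0 gives pure noise.
#' @param noise_fraction Fraction of features carrying no class signal.
#' @param seed Integer seed; output is a deterministic function of all
#'   arguments.
#' @return A list of class `rwce_simulation`: `views` (named list of tibbles,
#'   first column `instance_id`), `truth` (tibble `instance_id`, `label`),
#'   and `centers` (per-view list of k x m_signal center matrices).
#' @examples
#' sim <- simulate_multiview(n = 60, k = 3, views = 2, features = 10,
#'                           separation = 8, seed = 1)
#' dplyr::count(sim$truth, label)
#' @export
simulate_multiview <- function(n = 300, k = 3, proportions = NULL,
                               views = 3, features = 50,
                               separation = 6, noise_fraction = 0.2,
                               seed = 1) {
  if (k > n) stop("k must not exceed n", call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (length(proportions) != k) stop("proportions must have length k", call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8) {
    stop("proportions must be nonnegative and sum to 1", call. = FALSE)
  }
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (noise_fraction < 0 || noise_fraction > 1) {
    stop("noise_fraction must lie in [0, 1]", call. = FALSE)
  }

  if (is.numeric(views)) {
    views <- lapply(seq_len(views), function(v) list())
  }
  view_specs <- lapply(seq_along(views), function(v) {
    s <- views[[v]]
    list(
      features = s$features %||% features,
      separation = s$separation %||% separation,
      noise_fraction = s$noise_fraction %||% noise_fraction,
      name = s$name %||% paste0("view", v)
    )
  })

  sizes <- round_proportions(n, proportions)
  labels <- rep.int(seq_len(k), sizes)
  ids <- sprintf("inst_%03d", seq_len(n))

  out_views <- list()
  centers <- list()
  for (v in seq_along(view_specs)) {
    vs <- view_specs[[v]]
    m <- vs$features
    m_signal <- round((1 - vs$noise_fraction) * m)
    sim <- with_rng(derive_seed(seed, v), {
      ctr <- make_centers(k, m_signal, vs$separation)
      x <- matrix(stats::rnorm(n * m), n, m)
      if (m_signal > 0) x[, seq_len(m_signal)] <- x[, seq_len(m_signal)] + ctr[labels, , drop = FALSE]
      list(x = x, ctr = ctr)
    })
    colnames(sim$x) <- sprintf("f%03d", seq_len(m))
    out_views[[vs$name]] <- tibble::tibble(instance_id = ids) |>
      dplyr::bind_cols(tibble::as_tibble(sim$x))
    centers[[vs$name]] <- sim$ctr
  }

  structure(
    list(
      views = out_views,
      truth = tibble::tibble(instance_id = ids, label = labels),
      centers = centers
    ),
    class = "rwce_simulation"
  )
}

# Largest-remainder rounding of n * proportions to integer class sizes.
round_proportions <- function(n, proportions) {
  raw <- n * proportions
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    frac <- raw - sizes
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    sizes[top] <- sizes[top] + 1
  }
  as.integer(sizes)
}

# k x m center matrix whose minimum pairwise distance equals `separation`
# (all-zero when separation == 0, k == 1, or m == 0).
make_centers <- function(k, m, separation) {
  if (m == 0) return(matrix(0, k, 0))
  ctr <- matrix(stats::rnorm(k * m), k, m)
  if (k < 2 || separation == 0) return(ctr * 0)
  dmin <- min(stats::dist(ctr))
  while (dmin < 1e-8) { # resample near-coincident draws
    ctr <- matrix(stats::rnorm(k * m), k, m)
    dmin <- min(stats::dist(ctr))
  }
  ctr * (separation / dmin)
}

#' @export
print.rwce_simulation <- function(x, ...) {
  cat(sprintf("<rwce_simulation> %d instances, %d latent clusters, %d view(s)\n",
              nrow(x$truth), max(x$truth$label), length(x$views)))
  for (nm in names(x$views)) {
    cat(sprintf("  %s: %d features\n", nm, ncol(x$views[[nm]]) - 1L))
  }
  invisible(x)
}

#' Simulate survival outcomes for a clustered cohort
#'
#' Event times are exponential with cluster-specific hazards
#' `baseline_hazard * hazard_ratios[label]`; censoring times are drawn
#' independently from Uniform(0, b), with b solved numerically so that the
#' expected censored fraction under the cohort's mean hazard equals
#' `censor_rate`.
#'
#' @param labels Integer cluster labels (values `1..k`).
#' @param hazard_ratios Positive per-cluster hazard multipliers, length
#'   `max(labels)`.
#' @param baseline_hazard Hazard of a cluster with ratio 1 (events per time
#'   unit). Default 1.
#' @param censor_rate Target censored fraction in `[0, 1)`; 0 disables
#'   censoring.
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `event` (1 = event, 0 = censored)
#'   and `label`.
#' @examples
#' sv <- simulate_survival(rep(1:2, each = 50), hazard_ratios = c(1, 4), seed = 1)
#' table(sv$event)
#' @export
simulate_survival <- function(labels, hazard_ratios, baseline_hazard = 1,
                              censor_rate = 0, seed = 1) {
  labels <- check_labels(labels)
  k <- max(labels)
  if (length(hazard_ratios) != k) {
    stop("hazard_ratios must have one entry per cluster (", k, ")", call. = FALSE)
  }
  if (any(hazard_ratios <= 0)) stop("hazard_ratios must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1) {
    stop("censor_rate must lie in [0, 1)", call. = FALSE)
  }
  rates <- baseline_hazard * hazard_ratios[labels]
  with_rng(derive_seed(seed, 97), {
    t_event <- stats::rexp(length(labels), rate = rates)
    if (censor_rate == 0) {
      tibble::tibble(time = t_event, event = 1L, label = labels)
    } else {
      b <- censor_bound(mean(rates), censor_rate)
      t_cens <- stats::runif(length(labels), 0, b)
      tibble::tibble(
        time = pmin(t_event, t_cens),
        event = as.integer(t_event <= t_cens),
        label = labels
      )
    }
  })
}

# Upper bound b of Uniform(0, b) censoring such that
# P(C < T) = (1 - exp(-rate * b)) / (rate * b) equals `target`.
censor_bound <- function(rate, target) {
  f <- function(b) (1 - exp(-rate * b)) / (rate * b) - target
  stats::uniroot(f, lower = 1e-9, upper = 1e9, tol = 1e-10)$root
}

`%||%` <- function(a, b) if (is.null(a)) b else a
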