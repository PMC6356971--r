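test_that("silhouette matches the brute-force double loop", {
  set.seed(14)
  x <- matrix(rnorm(40), 20, 2)
  labels <- sample(1:3, 20, replace = TRUE)
  labels[1:3] <- 1:3                          # ensure all clusters occupied
  expect_equal(silhouette_mean(x, labels), oracle_silhouette(x, labels),
               tolerance = 1e-12)
  if (requireNamespace("cluster", quietly = TRUE)) {
    sil <- cluster::silhouette(labels, dist(x))
    expect_equal(silhouette_mean(x, labels), mean(sil[, "sil_width"]),
                 tolerance = 1e-12)
  }
})

test_that("silhouette hits its limit cases", {
  # two tight point-masses far apart -> s near 1
  x <- rbind(matrix(rnorm(20, sd = 1e-4), 10, 2),
             matrix(rnorm(20, 100, sd = 1e-4), 10, 2))
  expect_gt(silhouette_mean(x, rep(1:2, each = 10)), 0.999)
  # random labels on isotropic noise -> near 0
  set.seed(6)
  y <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(silhouette_mean(y, sample(1:3, 500, replace = TRUE))), 0.1)
  expect_error(silhouette_mean(y, rep(1, 500)), "2 clusters")
  # isometry invariance: rotation + translation leaves the score unchanged
  set.seed(7)
  z <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:2, 15)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(silhouette_mean(z, lab),
               silhouette_mean(z %*% rot + 5, lab), tolerance = 1e-12)
})

test_that("log-rank reproduces a hand-worked 10-patient table", {
  time <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  grp <- rep(1:2, each = 5)
  # frozen value computed from the O-E / variance definition by direct
  # accumulation over the 7 distinct event times
  lr <- logrank_test(time, event, grp)
  expect_equal(lr$statistic, 0.395550418954, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(0.395550418954, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(lr$df, 1L)
})

test_that("log-rank degenerate inputs behave", {
  # identical survival in both groups: duplicated data -> statistic 0, p 1
  time <- rep(c(2, 4, 6, 8), 2)
  event <- rep(c(1, 1, 0, 1), 2)
  lr <- logrank_test(time, event, rep(1:2, each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
  expect_error(logrank_test(1:4, rep(0, 4), rep(1:2, 2)), "no events")
  expect_error(logrank_test(1:4, rep(1, 4), rep(1, 4)), "2 groups")
  # three groups use the 2-df generalization
  lr3 <- logrank_test(c(1:9), c(rep(1, 9)), rep(1:3, each = 3))
  expect_equal(lr3$df, 2L)
})

test_that("adjusted Rand matches the contingency closed form and mclust", {
  a <- rep(1:3, times = c(4, 3, 3))
  b <- c(1, 1, 2, 2, 2, 2, 3, 3, 3, 1)
  expect_equal(adjusted_rand(a, b), 1 / 11, tolerance = 1e-12)  # hand-computed
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(8)
    for (i in 1:5) {
      p <- sample(1:4, 50, replace = TRUE)
      q <- sample(1:3, 50, replace = TRUE)
      expect_equal(adjusted_rand(p, q), mclust::adjustedRandIndex(p, q),
                   tolerance = 1e-12)
      expect_equal(adjusted_rand(p, q), adjusted_rand(q, p))  # symmetry
    }
  }
  expect_equal(adjusted_rand(1:10, rep(c(2, 9), 5) * 3), adjusted_rand(1:10, rep(c(1, 2), 5)))
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_error(adjusted_rand(1:4, 1:5), "equal length")
})

test_that("independent random partitions have ARI near zero in expectation", {
  set.seed(15)
  vals <- replicate(200, {
    adjusted_rand(sample(1:3, 100, replace = TRUE), sample(1:3, 100, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("evaluate_clustering assembles a tidy one-row report", {
  sim <- simulate_multiview(n = 60, k = 2, views = 1, features = 6,
                            separation = 8, noise_fraction = 0, seed = 2)
  sv <- simulate_survival(sim$truth$label, hazard_ratios = c(1, 4), seed = 2)
  rep <- evaluate_clustering(sim$views[[1]], sim$truth$label,
                             truth = sim$truth$label, survival = sv)
  expect_s3_class(rep, "tbl_df")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$ari, 1)
  expect_gt(rep$silhouette, 0.5)
  expect_lt(rep$logrank_p, 0.05)
})
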