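test_that("bipartite assembly is symmetric, block-anti-diagonal and guarded", {
  ric <- rbind(c(1, 0), c(0, 1))
  w <- build_bipartite(ric)
  expect_equal(dim(w), c(4, 4))
  expect_true(isSymmetric(w))
  expect_equal(w[1:2, 1:2], matrix(0, 2, 2))   # instance-instance block
  expect_equal(w[3:4, 3:4], matrix(0, 2, 2))   # cluster-cluster block
  expect_equal(w[1:2, 3:4], ric)

  ones <- matrix(1, 3, 2)
  w1 <- build_bipartite(ones)
  expect_equal(sum(w1), 2 * 6)                  # complete bipartite, unit weights
  expect_error(build_bipartite(rbind(c(1, 0), c(0, 0), c(0, 1))), "all-zero")
  expect_warning(build_bipartite(rbind(c(1, 0, 0), c(1, 0, 1))), "isolated cluster")
})

test_that("normalized Laplacian eigenvalues are bounded and count components", {
  set.seed(21)
  for (c_true in 2:4) {
    # block-diagonal bipartite graph with c_true disconnected components
    ric <- matrix(0, 6 * c_true, 2 * c_true)
    for (b in seq_len(c_true)) {
      rows <- (b - 1) * 6 + 1:6
      cols <- (b - 1) * 2 + 1:2
      ric[rows, cols] <- matrix(runif(12, 0.5, 1), 6, 2)
    }
    w <- build_bipartite(ric)
    fit <- spectral_partition(w, k = "auto", seed = 1)
    lam <- fit$eigenvalues
    expect_true(all(lam >= 0 & lam <= 2 + 1e-10))
    expect_equal(sum(lam < 1e-8), oracle_components(w))
    expect_equal(sum(lam < 1e-8), c_true)
    expect_equal(fit$chosen_k, c_true)
    # labels equal the components (the exact normalized-cut optimum)
    comp <- rep(seq_len(c_true), each = 6)
    expect_equal(adjusted_rand(fit$labels, comp), 1)
  }
})

test_that("complete bipartite graph has lambda_2 bounded away from zero", {
  w <- build_bipartite(matrix(1, 5, 4))
  fit <- spectral_partition(w, k = 2, seed = 1)
  expect_gt(fit$eigenvalues[2], 0.1)
  expect_lt(fit$eigenvalues[1], 1e-10)
})

test_that("eigengap tie-breaking prefers fewer clusters", {
  expect_equal(eigengap_k(c(0, 0, 1, 1, 2, 2)), 2L)       # gaps tie at i = 2 and 4
  expect_equal(eigengap_k(c(0, 0.01, 0.02, 0.9, 1, 1.1)), 3L)
  expect_equal(eigengap_k(c(0, 0, 0, 1, 1, 1), eigengap_max = 4), 3L)
})

test_that("partition labels are invariant to clustering order in the ensemble", {
  blobs <- make_blobs(n_per = 8, k = 3, sep = 12, seed = 5)
  ens <- generate_base_clusterings(blobs$x, ensemble_size = 8,
                                   k_min = 2, k_max = 4, seed = 3)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ens_perm <- as_ensemble(ens$labels[, perm])
  cfg <- rwce_config(seed = 9)
  f1 <- rwce_refine(ens, cfg)
  f2 <- rwce_refine(ens_perm, cfg)
  expect_equal(adjusted_rand(f1$labels, f2$labels), 1)
})

test_that("auto k recovers the group count on separable multi-view fixtures", {
  for (c_true in 2:4) {
    sim <- simulate_multiview(n = 40 * c_true, k = c_true, views = 1,
                              features = 15, separation = 9,
                              noise_fraction = 0, seed = 10 + c_true)
    fit <- run_single_view(sim$views[[1]],
                           rwce_config(ensemble_size = 12, seed = 10 + c_true))
    expect_equal(fit$chosen_k, c_true)
    expect_equal(adjusted_rand(fit$labels, sim$truth$label), 1)
  }
})
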