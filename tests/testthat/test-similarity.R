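test_that("Jaccard network matches set arithmetic and brute-force oracle", {
  # Lx = {1,2,3}, Ly = {2,3,4} in different clusterings -> 2/4
  ens <- as_ensemble(cbind(c(1, 1, 1, 2, 2), c(1, 2, 2, 2, 1)))
  ic <- pool_to_ic(ens)
  j <- jaccard_network(ic)
  expect_equal(j[1, 4], 0.5)          # {1,2,3} vs {2,3,4}
  expect_equal(j[1, 2], 0)            # disjoint, same clustering
  expect_equal(diag(j), rep(1, 4))
  expect_true(isSymmetric(j))

  set.seed(9)
  labs <- cbind(sample(rep(1:3, length.out = 12)), sample(rep(1:4, length.out = 12)))
  ic2 <- pool_to_ic(as_ensemble(labs))
  expect_equal(jaccard_network(ic2), oracle_jaccard(ic2), tolerance = 1e-14)
})

test_that("identical clusters across clusterings get Jaccard 1 and blocks stay zero", {
  labs <- rep(1:2, each = 4)
  ic <- pool_to_ic(as_ensemble(cbind(labs, labs)))
  j <- jaccard_network(ic)
  expect_equal(j[1, 3], 1)  # same instance set in both clusterings
  expect_equal(j[2, 4], 1)
  for (blk in attr(ic, "blocks")) {
    off <- j[blk, blk]; diag(off) <- 0
    expect_true(all(off == 0))
  }
})

test_that("random walk reaches the closed-form fixed point", {
  set.seed(5)
  labs <- cbind(sample(rep(1:2, 3)), sample(rep(1:3, 2)))
  ic <- pool_to_ic(as_ensemble(labs))       # n = 6, K_total = 5
  j <- jaccard_network(ic)
  f <- random_walk_restart(ic, j, alpha = 0.9, tol = 1e-12)
  expect_equal(unname(f[, ]), unname(oracle_rwr(ic * 1, j, 0.9)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # fixed-point residual under the update map
  a_hat <- j / rowSums(j)
  resid <- max(abs(0.9 * f %*% a_hat + 0.1 * ic - f))
  expect_lt(resid, 1e-6)
  expect_true(all(f >= 0))
})

test_that("random walk limit cases: alpha 0 and identity transition", {
  ic <- pool_to_ic(as_ensemble(cbind(rep(1:2, each = 3), rep(1:3, each = 2))))
  f0 <- random_walk_restart(ic, jaccard_network(ic), alpha = 0)
  expect_equal(unname(f0[, ]), unname(ic * 1), ignore_attr = TRUE)
  # identity adjacency: F = alpha F + (1 - alpha) F0 has fixed point F0
  fi <- random_walk_restart(ic, diag(ncol(ic)), alpha = 0.8, tol = 1e-12)
  expect_equal(unname(fi[, ]), unname(ic * 1), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(random_walk_restart(ic, jaccard_network(ic), alpha = 1), "alpha")
})

test_that("unnormalized walk errors on divergence instead of returning garbage", {
  ic <- pool_to_ic(as_ensemble(cbind(rep(1:2, each = 4), rep(1:2, times = 4))))
  j <- jaccard_network(ic)   # spectral radius > 1/alpha once alpha large
  expect_error(
    random_walk_restart(ic, j * 3, alpha = 0.9, normalize = FALSE, max_iter = 200),
    "diverged|converge"
  )
})

test_that("kernel similarity matches the double-loop oracle and its limits", {
  set.seed(3)
  walked <- matrix(rnorm(48), 8, 6)
  s <- kernel_similarity(walked, sigma = 1)
  expect_equal(s, oracle_kernel(walked, 1), tolerance = 1e-12)
  expect_equal(diag(s), rep(1, 6))
  expect_true(isSymmetric(s))
  expect_true(all(s > 0 & s <= 1))
  # rho^2 = 2, sigma = 1 -> exp(-1)
  w2 <- cbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(kernel_similarity(w2, 1)[1, 2], exp(-1))
  expect_error(kernel_similarity(walked, sigma = 0), "sigma")
})

test_that("kernel similarity decreases strictly with squared distance", {
  d2 <- seq(0, 10, by = 0.5)
  sims <- exp(-d2 / 2)
  walked <- rbind(sqrt(d2), matrix(0, 3, length(d2)))  # col i at distance sqrt(d2[i]) from col 1
  s <- kernel_similarity(walked, sigma = 1)[1, ]
  expect_equal(s, sims, tolerance = 1e-12)
  expect_true(all(diff(s[-1]) < 0))
})
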