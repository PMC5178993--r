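test_that("standardize uses the population (ddof = 0) convention", {
  X <- phenotype_matrix(cbind(a = c(1, 2, 3), b = c(4, 0, 2)))
  s <- standardize(X)
  expect_equal(unname(s$values[, "a"]), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  expect_equal(unname(colMeans(s$values)), c(0, 0), tolerance = 1e-12)
  # idempotent on already standardized data
  s2 <- standardize(s$values)
  expect_equal(s2$values, s$values, tolerance = 1e-12)
  expect_error(standardize(cbind(ok = 1:5, flat = rep(2, 5))), "flat")
})

test_that("pca returns orthonormal weights and sorted variance shares", {
  X <- low_rank_pheno(200, 6, 6, noise = 0, seed = 51)
  s <- standardize(X)
  d <- pca(s, "all")
  expect_equal(nrow(d$W), 6)                       # k = "all" -> m components
  expect_equal(unname(d$W %*% t(d$W)), diag(6), tolerance = 1e-8)
  expect_true(all(diff(d$explained_variance) <= 1e-12))
  expect_equal(sum(d$explained_variance), 1, tolerance = 1e-8)
  # full-rank reconstruction is exact
  expect_lt(max(abs(s$values - d$M %*% d$W)), 1e-8)
  expect_error(pca(s, 7), "exceeds")
  # perfectly correlated pair: one component carries everything
  z <- rnorm(100)
  d2 <- pca(standardize(cbind(t1 = z, t2 = 2 * z + 1)), "all")
  expect_equal(d2$explained_variance[1], 1, tolerance = 1e-10)
  # isotropic data: shares all near 1/m
  set.seed(52)
  d3 <- pca(standardize(matrix(rnorm(10000 * 4), ncol = 4)), "all")
  expect_true(all(abs(d3$explained_variance - 0.25) < 0.05 * 0.25 * 4))
})

test_that("choose_k_cv finds the latent dimension and is deterministic", {
  set.seed(53)
  Z <- matrix(rnorm(500 * 3), 500, 3) %*% matrix(rnorm(3 * 9), 3, 9) +
    0.25 * matrix(rnorm(500 * 9), 500, 9)
  s <- standardize(Z)
  cv <- choose_k_cv(s, k_max = 8, seed = 54)
  expect_equal(cv$k, 3)
  expect_identical(choose_k_cv(s, k_max = 8, seed = 54)$press_curve,
                   cv$press_curve)
  # pure noise: PRESS does not reward extra components
  set.seed(55)
  noise <- standardize(matrix(rnorm(300 * 6), 300, 6))
  cvn <- choose_k_cv(noise, k_max = 4, seed = 56)
  expect_true(cvn$k == 1 || all(diff(cvn$press_curve[-1]) >= 0))
  expect_error(choose_k_cv(s, k_max = 9), "k_max")
})

test_that("fastica recovers independent non-Gaussian sources", {
  set.seed(57)
  n <- 5000
  S <- cbind(runif(n, -sqrt(3), sqrt(3)), (rexp(n) - rexp(n)) / sqrt(2))
  A <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  s <- standardize(S %*% A)
  d <- fastica(s, 2, seed = 58)
  Aeff <- A %*% diag(1 / s$scale)    # mixing in standardized coordinates
  expect_lt(amari_index(Aeff %*% d$unmixing), 0.05)
  # scores: unit variance, zero mean, uncorrelated
  expect_equal(unname(colMeans(d$M)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(d$M, 2, function(x) mean(x^2))), c(1, 1),
               tolerance = 1e-6)
  expect_lt(abs(cor(d$M)[1, 2]), 1e-6)
  # determinism
  expect_identical(fastica(s, 2, seed = 58)$W, d$W)
})

test_that("ICA reconstruction residual equals the PCA residual at equal k", {
  X <- nongaussian_pheno(300, 7, 4, noise = 0.3, seed = 59)
  s <- standardize(X)
  for (k in c(2, 4)) {
    dp <- pca(s, k)
    di <- fastica(s, k, seed = 60)
    rp <- sum((s$values - dp$M %*% dp$W)^2)
    ri <- sum((s$values - di$M %*% di$W)^2)
    expect_equal(ri, rp, tolerance = 1e-8)
  }
})

test_that("the failure path triggers after exhausted restarts", {
  set.seed(61)
  g <- standardize(matrix(rnorm(400 * 3), 400, 3))
  expect_error(fastica(g, 3, seed = 62, tol = 1e-14, max_iter = 3),
               "failed to converge")
})

test_that("orient_and_order fixes signs, sorts, and is idempotent", {
  X <- nongaussian_pheno(200, 5, 3, noise = 0.4, seed = 63)
  s <- standardize(X)
  d <- orient_and_order(fastica(s, 3, seed = 64))
  for (i in 1:3) {
    j <- which.max(abs(d$W[i, ]))
    expect_gt(d$W[i, j], 0)          # dominant loading positive
  }
  expect_true(all(diff(d$explained_variance) <= 1e-12))
  expect_equal(d$component_labels, c("C1", "C2", "C3"))
  expect_equal(orient_and_order(d), d)
  # PCA order is already canonical
  dp <- pca(s, 3)
  expect_equal(orient_and_order(dp)$W, dp$W)
  # reconstruction unchanged by reorientation
  expect_equal(d$M %*% d$W, fastica(s, 3, seed = 64)$M %*%
                 fastica(s, 3, seed = 64)$W, tolerance = 1e-10)
})

test_that("orientation makes well-separated ICA seed-invariant", {
  set.seed(65)
  n <- 2000
  S <- cbind(runif(n, -sqrt(3), sqrt(3)), (rexp(n) - rexp(n)) / sqrt(2))
  s <- standardize(S %*% matrix(c(1, 0.2, 0.6, 1), 2, 2))
  # tight tol so both runs land on the same fixed point to 1e-5
  d1 <- orient_and_order(fastica(s, 2, seed = 1, tol = 1e-8))
  d2 <- orient_and_order(fastica(s, 2, seed = 999, tol = 1e-8))
  expect_equal(d1$W, d2$W, tolerance = 1e-5)
})
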