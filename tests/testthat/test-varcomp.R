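test_that("with identity relationship the fit collapses to OLS", {
  # Phi = I/2 makes 2*Phi = I, so the profiled likelihood equals the
  # closed-form Gaussian linear model at any h2; check 50 random instances
  set.seed(71)
  for (rep in 1:50) {
    n <- 40
    K <- structure(diag(n) / 2, dimnames = list(1:n, 1:n))
    Cmat <- cbind(x = rnorm(n))
    y <- 1 + 0.5 * Cmat[, 1] + rnorm(n)
    fit <- fit_polygenic(y, Cmat, K)
    ols <- lm(y ~ Cmat)
    s2 <- mean(residuals(ols)^2)
    ll_ols <- -n / 2 * (log(2 * pi * s2) + 1)
    expect_equal(fit$loglik, ll_ols, tolerance = 1e-6)
    expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-4)
  }
})

test_that("heritability estimates recover the simulated value", {
  ped <- simulate_pedigrees(21, 19, 3, seed = 72)
  K <- kinship_matrix(ped)
  eig <- kinship_eigen(K)
  L <- kinship_chol(K)
  set.seed(73)
  est <- replicate(60, fit_polygenic(simulate_polygenic_y(L, 0.5),
                                     K = eig)$h2)
  expect_lt(abs(mean(est) - 0.5), 0.07)
  # pure-noise traits rarely look heritable
  null_est <- replicate(60, fit_polygenic(rnorm(nrow(ped)), K = eig)$h2)
  expect_gt(mean(null_est < 0.05), 0.5)
})

test_that("heritability result follows the boundary-mixture definition", {
  ped <- simulate_pedigrees(8, 12, 3, seed = 74)
  eig <- kinship_eigen(kinship_matrix(ped))
  set.seed(75)
  h <- heritability(simulate_polygenic_y(kinship_chol(kinship_matrix(ped)),
                                         0.6), K = eig, label = "C1")
  expect_equal(h$h2r, h$sigma_g2 / (h$sigma_g2 + h$sigma_e2),
               tolerance = 1e-8)
  expect_equal(h$metaphenotype_label, "C1")
  # lrt = 0 maps to p = 0.5 under 0.5*chi2_0 + 0.5*chi2_1
  expect_equal(0.5 * pchisq(0, 1, lower.tail = FALSE), 0.5)
  expect_true(h$p_value > 0 && h$p_value <= 1)
})

test_that("association LRT is invariant to affine rescaling of y", {
  ped <- simulate_pedigrees(6, 10, 3, seed = 76)
  eig <- kinship_eigen(kinship_matrix(ped))
  G <- drop_genotypes(ped, 3, 0.3, seed = 77)
  set.seed(78)
  y <- simulate_polygenic_y(kinship_chol(kinship_matrix(ped)), 0.4) +
    0.3 * G$values[, 1]
  a1 <- assoc_snp(y, K = eig, g = G$values[, 1], snp_id = "snp0001")
  a2 <- assoc_snp(100 + 7 * y, K = eig, g = G$values[, 1], snp_id = "snp0001")
  expect_equal(a1$lrt_stat, a2$lrt_stat, tolerance = 1e-5)
  expect_equal(a1$p_raw, pchisq(a1$lrt_stat, 1, lower.tail = FALSE))
})

test_that("monomorphic and missing genotypes are handled per contract", {
  ped <- simulate_pedigrees(5, 10, 3, seed = 79)
  n <- nrow(ped)
  eig <- kinship_eigen(kinship_matrix(ped))
  set.seed(80)
  y <- rnorm(n)
  mono <- assoc_snp(y, K = eig, g = rep(1, n), snp_id = "flat")
  expect_false(mono$testable)
  expect_true(is.na(mono$p_raw))
  # complete-case per SNP: missing genotypes are dropped from the fit
  g <- rbinom(n, 2, 0.4); g[1:5] <- NA
  a <- assoc_snp(y, K = eig, g = g, snp_id = "s")
  expect_equal(a$n_used, n - 5)
})

test_that("gwas applies Bonferroni over testable pairs and caps at 1", {
  ped <- simulate_pedigrees(6, 12, 3, seed = 81)
  eig <- kinship_eigen(kinship_matrix(ped))
  G <- drop_genotypes(ped, 5, 0.3, seed = 82)
  G$values[, 5] <- 0                      # monomorphic: not testable
  set.seed(83)
  M <- cbind(C1 = rnorm(nrow(ped)), C2 = rnorm(nrow(ped)))
  res <- gwas(M, G, K = eig, alpha = 0.05)
  expect_equal(nrow(res), 4 * 2)          # monomorphic SNP excluded
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 8), tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$lrt_stat >= 0))
  # per-metaphenotype correction divides the multiplicity by k
  res2 <- gwas(M, G, K = eig, correction = "per_metaphenotype")
  expect_equal(res2$p_adjusted, pmin(1, res2$p_raw * 4), tolerance = 1e-12)
})

test_that("a strong SNP effect is detected through the mixed model", {
  ped <- simulate_pedigrees(21, 19, 3, seed = 84)
  K <- kinship_matrix(ped)
  eig <- kinship_eigen(K)
  G <- drop_genotypes(ped, 2, 0.3, seed = 85)
  set.seed(86)
  g <- G$values[, 1]
  y <- sqrt(0.2) * drop(scale(g)) +
    sqrt(0.8) * simulate_polygenic_y(kinship_chol(K), 0.4)
  a <- assoc_snp(y, K = eig, g = g, snp_id = "snp0001", label = "C1")
  expect_lt(a$p_raw, 1e-6)
  expect_gt(a$beta_snp, 0)
})

test_that("singular designs are rejected", {
  ped <- simulate_pedigrees(3, 8, 2, seed = 87)
  eig <- kinship_eigen(kinship_matrix(ped))
  n <- nrow(ped)
  Cmat <- cbind(a = rep(1, n), b = rep(2, n))  # collinear with intercept
  expect_error(fit_polygenic(rnorm(n), Cmat, eig), "singular")
})
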