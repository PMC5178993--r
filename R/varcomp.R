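# Polygenic variance-components model
#   y ~ N(X beta, sigma_g2 * 2*Phi + sigma_e2 * I)
# fitted by full maximum likelihood: 2*Phi is diagonalized once, the model
# is rotated into the eigenbasis, and the likelihood is profiled over beta
# and the total variance, leaving a 1-D optimization over the heritability
# ratio h2 = sigma_g2 / (sigma_g2 + sigma_e2), constrained to [0, 1).
# Full ML (not REML) throughout so likelihood-ratio tests of fixed effects
# (the SNP term) are valid.

#' @keywords internal
polygenic_profile_ll <- function(h2, yt, Xt, d) {
  n <- length(yt)
  v <- h2 * d + (1 - h2)
  w <- 1 / v
  XtW <- Xt * w
  XX <- crossprod(Xt, XtW)
  beta <- solve(XX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  s2 <- sum(w * r^2) / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(v)) + n)
  list(ll = ll, beta = beta, s2 = s2)
}

#' @keywords internal
polygenic_ml <- function(y, X, eig) {
  n <- length(y)
  stopifnot(nrow(X) == n, length(eig$values) == n)
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design matrix")
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  d <- eig$values
  f <- function(h2) polygenic_profile_ll(h2, yt, Xt, d)$ll
  opt <- stats::optimize(f, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  ll_boundary <- f(0)
  if (ll_boundary >= opt$objective) h2 <- 0
  fit <- polygenic_profile_ll(h2, yt, Xt, d)
  list(h2 = h2, sigma_g2 = h2 * fit$s2, sigma_e2 = (1 - h2) * fit$s2,
       beta = drop(fit$beta), loglik = fit$ll, converged = TRUE)
}

#' @keywords internal
design_matrix <- function(n, C, snp = NULL) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(C)) X <- cbind(X, as.matrix(C))
  if (!is.null(snp)) X <- cbind(X, snp = snp)
  X
}

#' Fit the polygenic mixed model for one trait
#'
#' @param y numeric response vector (no missing values), aligned with the
#'   rows of `K`.
#' @param C optional covariate matrix (age, sex, ...), same row order; an
#'   intercept is always added.
#' @param K kinship matrix from [kinship_matrix] (its eigen decomposition is
#'   computed here), or a precomputed [kinship_eigen] object.
#' @param snp optional additively coded genotype column; individuals with a
#'   missing genotype are dropped from this fit (complete-case per SNP).
#' @return A list of class `varcomp_fit`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `beta` (intercept, covariates, then `snp` if given), `loglik`,
#'   `converged`, `n_used`.
#' @export
fit_polygenic <- function(y, C = NULL, K, snp = NULL) {
  stopifnot(is.numeric(y), !anyNA(y))
  eig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  keep <- if (is.null(snp)) rep(TRUE, length(y)) else !is.na(snp)
  if (!all(keep)) {
    A <- (eig$vectors %*% (t(eig$vectors) * eig$values))[keep, keep]
    e <- eigen(A, symmetric = TRUE)
    eig <- list(vectors = e$vectors, values = pmax(e$values, 0))
  }
  X <- design_matrix(sum(keep), if (is.null(C)) NULL else
    as.matrix(C)[keep, , drop = FALSE],
    if (is.null(snp)) NULL else snp[keep])
  fit <- polygenic_ml(y[keep], X, eig)
  fit$n_used <- sum(keep)
  class(fit) <- "varcomp_fit"
  fit
}

#' Heritability of a trait with a boundary-corrected likelihood-ratio test
#'
#' h2r is estimated from the unconstrained ML fit; the p-value tests
#' sigma_g2 = 0 by an LRT referred to the boundary mixture
#' 0.5 chi2(0) + 0.5 chi2(1).
#'
#' @inheritParams fit_polygenic
#' @param label optional metaphenotype label carried into the result.
#' @return A list of class `heritability_result`: `metaphenotype_label`,
#'   `h2r`, `p_value`, `lrt_stat`, `sigma_g2`, `sigma_e2`.
#' @export
heritability <- function(y, C = NULL, K, label = NA_character_) {
  eig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  X <- design_matrix(length(y), C)
  yt <- crossprod(eig$vectors, y)
  Xt <- crossprod(eig$vectors, X)
  fit <- polygenic_ml(y, X, eig)
  ll0 <- polygenic_profile_ll(0, yt, Xt, eig$values)$ll
  lrt <- max(2 * (fit$loglik - ll0), 0)
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(metaphenotype_label = label,
                 h2r = fit$h2, p_value = p, lrt_stat = lrt,
                 sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2),
            class = "heritability_result")
}

#' Likelihood-ratio association test of one SNP against one trait
#'
#' Both the null (covariates only) and the alternative (covariates + SNP)
#' model are fitted by full ML on the same complete-case individuals; the
#' LRT statistic is referred to chi2(1).
#'
#' @inheritParams fit_polygenic
#' @param g additively coded genotype column (0/1/2, `NA` allowed).
#' @param snp_id,label identifiers carried into the result.
#' @return A list of class `assoc_fit`: `snp_id`, `metaphenotype_label`,
#'   `beta_snp`, `lrt_stat`, `p_raw`, `n_used`, `testable`.
#' @export
assoc_snp <- function(y, C = NULL, K, g, snp_id = NA_character_,
                      label = NA_character_) {
  keep <- !is.na(g)
  gk <- g[keep]
  if (length(unique(gk)) < 2)
    return(structure(list(snp_id = snp_id, metaphenotype_label = label,
                          beta_snp = NA_real_, lrt_stat = NA_real_,
                          p_raw = NA_real_, n_used = sum(keep),
                          testable = FALSE), class = "assoc_fit"))
  eig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  if (!all(keep)) {
    A <- (eig$vectors %*% (t(eig$vectors) * eig$values))[keep, keep]
    e <- eigen(A, symmetric = TRUE)
    eig <- list(vectors = e$vectors, values = pmax(e$values, 0))
  }
  Ck <- if (is.null(C)) NULL else as.matrix(C)[keep, , drop = FALSE]
  fit0 <- polygenic_ml(y[keep], design_matrix(sum(keep), Ck), eig)
  fit1 <- polygenic_ml(y[keep], design_matrix(sum(keep), Ck, gk), eig)
  lrt <- 2 * (fit1$loglik - fit0$loglik)
  if (lrt < -1e-8)
    warning("negative LRT statistic (", lrt, ") for ", snp_id)
  lrt <- max(lrt, 0)
  structure(list(snp_id = snp_id, metaphenotype_label = label,
                 beta_snp = unname(fit1$beta[length(fit1$beta)]),
                 lrt_stat = lrt,
                 p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 n_used = sum(keep), testable = TRUE),
            class = "assoc_fit")
}

#' Mixed-model GWAS of metaphenotype scores with Bonferroni correction
#'
#' Runs [assoc_snp] for every (SNP, metaphenotype) pair. P-values are
#' Bonferroni-adjusted over all testable pairs jointly by default
#' (`correction = "global"`), or per metaphenotype.
#'
#' @param M numeric matrix of component scores (individuals x components),
#'   columns named by metaphenotype label.
#' @param G a [genotype_matrix] aligned with the rows of `M`.
#' @param C optional covariate matrix.
#' @param K kinship matrix or [kinship_eigen].
#' @param alpha significance level applied to adjusted p-values.
#' @param correction `"global"` (SNPs x metaphenotypes) or
#'   `"per_metaphenotype"`.
#' @return A data.frame of class `assoc_result` with one row per testable
#'   pair: snp_id, chromosome, position, metaphenotype, maf, beta,
#'   lrt_stat, p_raw, p_adjusted, significant, n_used.
#' @export
gwas <- function(M, G, C = NULL, K, alpha = 0.05,
                 correction = c("global", "per_metaphenotype")) {
  correction <- match.arg(correction)
  M <- as.matrix(M)
  stopifnot(inherits(G, "genotype_matrix"), nrow(M) == nrow(G$values))
  labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("C", seq_len(ncol(M)))
  eig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  # null model depends only on the metaphenotype when the SNP is complete
  null_fits <- lapply(seq_len(ncol(M)), function(j)
    polygenic_ml(M[, j], design_matrix(nrow(M), C), eig))
  rows <- list()
  for (s in seq_len(ncol(G$values))) {
    g <- G$values[, s]
    snp_maf <- if (all(is.na(g))) NA_real_ else maf(g)
    complete <- !anyNA(g)
    for (j in seq_len(ncol(M))) {
      a <- if (complete && length(unique(g)) >= 2) {
        fit1 <- polygenic_ml(M[, j], design_matrix(nrow(M), C, g), eig)
        lrt <- max(2 * (fit1$loglik - null_fits[[j]]$loglik), 0)
        list(snp_id = G$markers$snp_id[s], metaphenotype_label = labels[j],
             beta_snp = unname(fit1$beta[length(fit1$beta)]),
             lrt_stat = lrt,
             p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
             n_used = length(g), testable = TRUE)
      } else assoc_snp(M[, j], C, eig, g, snp_id = G$markers$snp_id[s],
                       label = labels[j])
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = a$snp_id, chromosome = G$markers$chromosome[s],
        position = G$markers$position[s], metaphenotype = a$metaphenotype_label,
        maf = snp_maf, beta = a$beta_snp, lrt_stat = a$lrt_stat,
        p_raw = a$p_raw, n_used = a$n_used, testable = a$testable,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[res$testable, , drop = FALSE]
  if (!nrow(res)) stop("no testable (SNP, metaphenotype) pair")
  n_tests <- if (correction == "global") nrow(res) else
    as.vector(table(res$metaphenotype)[res$metaphenotype])
  res$p_adjusted <- pmin(1, res$p_raw * n_tests)
  res$significant <- res$p_adjusted <= alpha
  res$testable <- NULL
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Heritability table for a set of metaphenotype scores
#'
#' @inheritParams gwas
#' @return A data.frame with metaphenotype, h2r, p_value, lrt_stat,
#'   sigma_g2, sigma_e2 and significance stars (0.05 / 0.005 / 0.0005).
#' @export
heritability_table <- function(M, C = NULL, K) {
  M <- as.matrix(M)
  labels <- colnames(M)
  if (is.null(labels)) labels <- paste0("C", seq_len(ncol(M)))
  eig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  out <- lapply(seq_len(ncol(M)), function(j) {
    h <- heritability(M[, j], C, eig, label = labels[j])
    data.frame(metaphenotype = labels[j], h2r = h$h2r, p_value = h$p_value,
               lrt_stat = h$lrt_stat, sigma_g2 = h$sigma_g2,
               sigma_e2 = h$sigma_e2,
               stars = if (h$p_value < 5e-4) "***" else
                 if (h$p_value < 5e-3) "**" else
                   if (h$p_value < 5e-2) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
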