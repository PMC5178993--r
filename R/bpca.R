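# Missing-value imputation of the trait matrix by Bayesian/probabilistic
# PCA. The model is y_i = mu + W x_i + eps with x ~ N(0, I_q) and isotropic
# residual; missing cells simply drop out of the likelihood, so EM here is
# exact for the observed-data likelihood (latent variables are the factor
# scores only). An automatic-relevance (ARD) Gaussian prior on each loading
# column shrinks superfluous columns toward zero, so q can default to m-1.
# Traits are z-scored on their observed cells before fitting and restored
# afterwards: the 27 coagulation assays this targets have incompatible units.

#' Fit a Bayesian PCA model to a phenotype matrix with missing values
#'
#' @param X a [phenotype_matrix]; every row and column must contain at least
#'   one observed value.
#' @param q number of latent components; default `m - 1` with ARD shrinkage
#'   selecting the effective dimensionality.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol convergence: maximum absolute change (in standardized units)
#'   of any imputed cell between iterations.
#' @param seed RNG seed for the loading initialization.
#' @return A list of class `bpca_model` with elements `loading_matrix`
#'   (m x q), `mean_vector`, `residual_variance`, `alpha` (ARD precisions),
#'   `center`, `scale`, `trait_names`, `converged`, `n_iterations`, and
#'   `objective` (penalized negative log-likelihood per iteration,
#'   non-increasing).
#' @export
fit_bpca <- function(X, q = NULL, max_iter = 500, tol = 1e-4, seed = 1) {
  stopifnot(inherits(X, "phenotype_matrix"))
  Y <- X$values
  n <- nrow(Y); m <- ncol(Y)
  if (any(rowSums(!is.na(Y)) == 0)) stop("row with no observed value")
  if (any(colSums(!is.na(Y)) == 0)) stop("column with no observed value")
  if (is.null(q)) q <- m - 1L
  stopifnot(q >= 0, q <= m - 1L)

  center <- colMeans(Y, na.rm = TRUE)
  scale <- apply(Y, 2, stats::sd, na.rm = TRUE)
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- sweep(sweep(Y, 2, center), 2, scale, "/")

  if (q == 0L) {   # degenerate fall-back: column-mean model
    model <- structure(list(
      loading_matrix = matrix(0, m, 0), mean_vector = colMeans(Z, na.rm = TRUE),
      residual_variance = 1, alpha = numeric(0), center = center,
      scale = scale, trait_names = X$trait_names, converged = TRUE,
      n_iterations = 0L, objective = numeric(0)), class = "bpca_model")
    return(model)
  }

  obs <- !is.na(Z)
  pat_key <- apply(obs, 1, paste, collapse = "")
  pats <- split(seq_len(n), pat_key)
  use_ard <- m >= 3L

  set.seed(seed)
  W <- matrix(stats::rnorm(m * q, sd = 0.1), m, q)
  mu <- rep(0, m)
  sigma2 <- 1
  alpha <- rep(if (use_ard) 1 else 0, q)
  Zimp <- Z; Zimp[!obs] <- 0
  prev_imp <- Zimp[!obs]
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    # E-step, grouped by missingness pattern: posterior mean/cov of the
    # factor scores under the current parameters
    Xbar <- matrix(0, n, q)
    Spost <- vector("list", length(pats))   # per-pattern posterior cov of x
    Sxx_obs_d <- array(0, c(q, q, m))       # sum over rows observing trait d
    for (p in seq_along(pats)) {
      rows <- pats[[p]]
      o <- obs[rows[1], ]
      Wo <- W[o, , drop = FALSE]
      Minv <- solve(crossprod(Wo) + sigma2 * diag(q))
      R <- sweep(Z[rows, o, drop = FALSE], 2, mu[o])  # rows x |o|
      xb <- R %*% Wo %*% Minv
      Xbar[rows, ] <- xb
      S <- sigma2 * Minv
      Spost[[p]] <- S
      acc <- crossprod(xb) + length(rows) * S
      for (d in which(o))
        Sxx_obs_d[, , d] <- Sxx_obs_d[, , d] + acc
    }

    # M-step (coordinate updates; each maximizes the penalized Q)
    for (d in seq_len(m)) {
      rows_d <- which(obs[, d])
      mu[d] <- mean(Z[rows_d, d] - Xbar[rows_d, , drop = FALSE] %*% W[d, ])
    }
    for (d in seq_len(m)) {
      rows_d <- which(obs[, d])
      A <- Sxx_obs_d[, , d] + sigma2 * diag(alpha, q)
      b <- crossprod(Xbar[rows_d, , drop = FALSE], Z[rows_d, d] - mu[d])
      W[d, ] <- solve(A, b)
    }
    rss <- 0; n_obs_cells <- 0
    for (p in seq_along(pats)) {
      rows <- pats[[p]]
      o <- obs[rows[1], ]
      Wo <- W[o, , drop = FALSE]
      R <- sweep(Z[rows, o, drop = FALSE], 2, mu[o])
      E <- R - Xbar[rows, , drop = FALSE] %*% t(Wo)
      # E[(y - mu - w'x)^2] = (y - mu - w'xbar)^2 + w' S w, S from the E-step
      rss <- rss + sum(E^2) +
        length(rows) * sum((Wo %*% Spost[[p]]) * Wo)
      n_obs_cells <- n_obs_cells + length(rows) * sum(o)
    }
    sigma2 <- max(rss / n_obs_cells, 1e-10)
    if (use_ard)
      alpha <- pmin((m - 2) / (colSums(W^2) + 1e-12), 1e8)

    # penalized negative observed-data log-likelihood (monotone non-increasing)
    objective <- c(objective, bpca_objective(Z, obs, pats, W, mu, sigma2,
                                             alpha, use_ard))

    # imputations and convergence check
    imp <- bpca_expected_missing(Z, obs, pats, W, mu, sigma2)
    delta <- max(abs(imp - prev_imp), 0)
    prev_imp <- imp
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("bPCA did not converge in ", max_iter, " iterations")

  structure(list(loading_matrix = W, mean_vector = mu,
                 residual_variance = sigma2, alpha = alpha,
                 center = center, scale = scale,
                 trait_names = X$trait_names, converged = converged,
                 n_iterations = iter, objective = objective),
            class = "bpca_model")
}

#' @keywords internal
bpca_expected_missing <- function(Z, obs, pats, W, mu, sigma2) {
  q <- ncol(W)
  out <- numeric(sum(!obs))
  miss_index <- which(!obs)
  fill <- matrix(NA_real_, nrow(Z), ncol(Z))
  for (rows in pats) {
    o <- obs[rows[1], ]
    if (all(o)) next
    Wo <- W[o, , drop = FALSE]
    Minv <- solve(crossprod(Wo) + sigma2 * diag(q))
    xb <- sweep(Z[rows, o, drop = FALSE], 2, mu[o]) %*% Wo %*% Minv
    pred <- sweep(xb %*% t(W[!o, , drop = FALSE]), 2, mu[!o], "+")
    fill[rows, !o] <- pred
  }
  fill[miss_index]
}

#' @keywords internal
bpca_objective <- function(Z, obs, pats, W, mu, sigma2, alpha, use_ard) {
  q <- ncol(W)
  nll <- 0
  for (rows in pats) {
    o <- obs[rows[1], ]
    Wo <- W[o, , drop = FALSE]
    M <- crossprod(Wo) + sigma2 * diag(q)
    R <- sweep(Z[rows, o, drop = FALSE], 2, mu[o])
    no <- sum(o)
    logdet <- (no - q) * log(sigma2) + determinant(M, logarithm = TRUE)$modulus
    quad <- (rowSums(R^2) - rowSums((R %*% Wo %*% solve(M)) * (R %*% Wo))) / sigma2
    nll <- nll + 0.5 * sum(quad) +
      length(rows) * 0.5 * (logdet + no * log(2 * pi))
  }
  if (use_ard) {
    m <- nrow(W)
    nll <- nll + sum(alpha * colSums(W^2) / 2 - (m / 2 - 1) * log(alpha))
  }
  as.numeric(nll)
}

#' Impute missing phenotype cells from a fitted bPCA model
#'
#' Observed cells are returned unchanged; missing cells are replaced by
#' their posterior expectation under the model. The output contains no
#' missing entries.
#'
#' @param X a [phenotype_matrix] on the same traits the model was fit to.
#' @param model a `bpca_model` from [fit_bpca].
#' @return A [phenotype_matrix] without missing values.
#' @export
impute <- function(X, model) {
  stopifnot(inherits(X, "phenotype_matrix"), inherits(model, "bpca_model"))
  if (!identical(X$trait_names, model$trait_names))
    stop("trait names of X do not match the fitted model")
  Y <- X$values
  if (!anyNA(Y)) return(X)
  Z <- sweep(sweep(Y, 2, model$center), 2, model$scale, "/")
  obs <- !is.na(Z)
  if (ncol(model$loading_matrix) == 0L) {     # mean model
    for (d in seq_len(ncol(Z))) Z[!obs[, d], d] <- model$mean_vector[d]
  } else {
    pat_key <- apply(obs, 1, paste, collapse = "")
    pats <- split(seq_len(nrow(Z)), pat_key)
    Z[!obs] <- bpca_expected_missing(Z, obs, pats, model$loading_matrix,
                                     model$mean_vector,
                                     model$residual_variance)
  }
  Yout <- sweep(sweep(Z, 2, model$scale, "*"), 2, model$center, "+")
  Yout[obs] <- Y[obs]   # observed cells bit-identical
  phenotype_matrix(Yout, X$trait_names, X$individual_ids, X$covariates)
}
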