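# Metaphenotype construction. Both PCA and ICA write the trait matrix as
# X = M W + E: M (n x k) holds the component scores (the metaphenotypes),
# W (k x m) the weights of each trait on each component. ICA is a rotation
# of the PCA-whitened space chosen to maximize non-Gaussianity (a negentropy
# approximation), so at equal k both methods share the same reconstruction
# residual. Population (1/n) variance convention throughout.

#' Column-standardize a phenotype matrix
#'
#' @param X a [phenotype_matrix] without missing values (impute first), or a
#'   plain numeric matrix.
#' @return A list with `values` (each column mean 0, population sd 1),
#'   `center` and `scale`.
#' @export
standardize <- function(X) {
  vals <- if (inherits(X, "phenotype_matrix")) X$values else as.matrix(X)
  if (anyNA(vals)) stop("standardize: missing values present; impute first")
  n <- nrow(vals)
  center <- colMeans(vals)
  sc <- sqrt(colMeans(sweep(vals, 2, center)^2))  # ddof = 0
  zero <- !is.finite(sc) | sc < 1e-12
  if (any(zero))
    stop("zero-variance trait(s): ",
         paste(colnames(vals)[zero], collapse = ", "))
  list(values = sweep(sweep(vals, 2, center), 2, sc, "/"),
       center = center, scale = sc)
}

#' @keywords internal
new_decomposition <- function(method, W, M, explained_variance, unmixing,
                              trait_names, center, scale) {
  k <- nrow(W)
  rownames(W) <- colnames(M) <- paste0("C", seq_len(k))
  structure(list(method = method, W = W, M = M,
                 explained_variance = explained_variance,
                 unmixing = unmixing,
                 trait_names = trait_names,
                 component_labels = paste0("C", seq_len(k)),
                 center = center, scale = scale),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("%s decomposition: %d components on %d traits\n", x$method,
              nrow(x$W), ncol(x$W)))
  ev <- round(100 * x$explained_variance, 1)
  cat("explained variance (%):", paste(ev, collapse = " "), "\n")
  invisible(x)
}

#' Principal component analysis of a standardized trait matrix
#'
#' @param Xs standardized matrix (from [standardize]) or the list it
#'   returns.
#' @param k number of components, or `"all"`.
#' @return A `decomposition`: rows of `W` are orthonormal eigenvectors of
#'   the sample covariance, scores `M = Xs W'`, `explained_variance` the
#'   eigenvalue shares (non-increasing).
#' @export
pca <- function(Xs, k = "all") {
  s <- as_standardized(Xs)
  Z <- s$values
  m <- ncol(Z); n <- nrow(Z)
  if (identical(k, "all")) k <- m
  if (k > m) stop("k = ", k, " exceeds the number of traits (", m, ")")
  C <- crossprod(Z) / n
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| trait positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  W <- t(V)
  colnames(W) <- colnames(Z)
  new_decomposition("PCA", W, Z %*% V,
                    e$values[seq_len(k)] / sum(e$values), V,
                    colnames(Z), s$center, s$scale)
}

#' @keywords internal
as_standardized <- function(Xs) {
  if (is.list(Xs) && !is.null(Xs$values) && !is.null(Xs$center)) return(Xs)
  if (inherits(Xs, "phenotype_matrix")) return(standardize(Xs))
  m <- as.matrix(Xs)
  list(values = m, center = rep(0, ncol(m)), scale = rep(1, ncol(m)))
}

#' Choose the number of components by element-wise cross-validation
#'
#' Wold-style: cells are partitioned at random into `n_folds` groups; for
#' each candidate k each group is deleted in turn, reconstructed by an
#' EM-PCA (iterated SVD imputation) of rank k fitted on the remaining
#' cells, and the squared prediction error accumulated (PRESS). The k with
#' minimal PRESS is returned.
#'
#' @param Xs standardized matrix or [standardize] output.
#' @param k_max largest candidate (must be below the number of traits).
#' @param n_folds number of random cell groups (>= 2).
#' @param seed RNG seed for the cell partition.
#' @return A list with `k` (argmin PRESS) and `press_curve` (length
#'   `k_max`).
#' @export
choose_k_cv <- function(Xs, k_max, n_folds = 5, seed = 1) {
  s <- as_standardized(Xs)
  Z <- s$values
  n <- nrow(Z); m <- ncol(Z)
  if (k_max >= m) stop("k_max must be < number of traits")
  stopifnot(n_folds >= 2)
  set.seed(seed)
  fold <- matrix(sample(rep_len(seq_len(n_folds), n * m)), n, m)
  press <- numeric(k_max)
  for (f in seq_len(n_folds)) {
    hold <- fold == f
    # never blank out an entire row or column
    bad_r <- rowSums(!hold) == 0; bad_c <- colSums(!hold) == 0
    if (any(bad_r)) hold[bad_r, ] <- FALSE
    if (any(bad_c)) hold[, bad_c] <- FALSE
    Zmiss <- Z; Zmiss[hold] <- NA
    for (k in seq_len(k_max)) {
      rec <- em_pca_reconstruct(Zmiss, k)
      press[k] <- press[k] + sum((rec[hold] - Z[hold])^2)
    }
  }
  list(k = which.min(press), press_curve = press)
}

#' Rank-k EM-PCA reconstruction of a matrix with missing cells
#'
#' Iterated SVD imputation: missing cells start at the column mean of the
#' observed cells and are refined by the rank-k truncated SVD until the
#' imputations stabilize.
#' @param Z numeric matrix with `NA` holes.
#' @param k target rank.
#' @param max_iter,tol iteration control.
#' @return The completed matrix (observed cells as given).
#' @export
em_pca_reconstruct <- function(Z, k, max_iter = 100, tol = 1e-4) {
  obs <- !is.na(Z)
  mu <- colSums(Z * obs, na.rm = TRUE) / pmax(colSums(obs), 1)
  Zi <- Z
  for (d in seq_len(ncol(Z))) Zi[!obs[, d], d] <- mu[d]
  for (it in seq_len(max_iter)) {
    cmean <- colMeans(Zi)
    Zc <- sweep(Zi, 2, cmean)
    sv <- svd(Zc, nu = k, nv = k)
    rec <- sweep(sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v)), 2, cmean, "+")
    delta <- max(abs(rec[!obs] - Zi[!obs]), 0)
    Zi[!obs] <- rec[!obs]
    if (delta < tol) break
  }
  Zi
}

#' FastICA by symmetric fixed-point iteration
#'
#' The data are whitened by PCA to `k` dimensions; an orthogonal rotation is
#' then sought by the fixed-point update that maximizes the negentropy
#' approximation E\[G(w'z)\], with G'(u) = tanh(u) (`logcosh`, default) or
#' G'(u) = u exp(-u^2/2) (`exp`), under symmetric decorrelation. On
#' non-convergence the iteration restarts (up to 5 times) from a perturbed
#' seed.
#'
#' @param Xs standardized matrix or [standardize] output.
#' @param k number of components.
#' @param seed RNG seed for the initial rotation.
#' @param contrast negentropy approximation, `"logcosh"` or `"exp"`.
#' @param tol convergence tolerance on the rotation (reference fastICA
#'   default, 1e-4).
#' @param max_iter maximum fixed-point iterations per restart.
#' @return A `decomposition` with unit-variance, uncorrelated scores `M`
#'   and weights `W` such that `M %*% W` equals the rank-k PCA
#'   reconstruction of `Xs`.
#' @export
fastica <- function(Xs, k, seed = 1, contrast = c("logcosh", "exp"),
                    tol = 1e-4, max_iter = 500) {
  contrast <- match.arg(contrast)
  s <- as_standardized(Xs)
  Z0 <- s$values
  n <- nrow(Z0); m <- ncol(Z0)
  if (k > m) stop("k = ", k, " exceeds the number of traits (", m, ")")
  C <- crossprod(Z0) / n
  e <- eigen(C, symmetric = TRUE)
  if (e$values[k] < 1e-10)
    stop("data have rank below k; reduce k")
  U <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]
  Kw <- U %*% diag(1 / sqrt(lam), k)       # whitening, m x k
  Z <- Z0 %*% Kw                           # n x k, unit variance, uncorrelated

  sym_decorrelate <- function(W) {
    es <- eigen(W %*% t(W), symmetric = TRUE)
    es$vectors %*% diag(1 / sqrt(pmax(es$values, 1e-300)), nrow(W)) %*%
      t(es$vectors) %*% W
  }
  g <- switch(contrast,
              logcosh = function(u) tanh(u),
              exp     = function(u) u * exp(-u^2 / 2))
  gprime <- switch(contrast,
                   logcosh = function(u) 1 - tanh(u)^2,
                   exp     = function(u) (1 - u^2) * exp(-u^2 / 2))

  Wrot <- NULL
  for (attempt in 0:4) {
    set.seed(seed + attempt * 1000L)
    Wc <- sym_decorrelate(matrix(stats::rnorm(k * k), k, k))
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      Y <- Z %*% t(Wc)
      GY <- g(Y)
      Wnew <- crossprod(GY, Z) / n - diag(colMeans(gprime(Y)), k) %*% Wc
      Wnew <- sym_decorrelate(Wnew)
      conv <- max(abs(1 - abs(rowSums(Wnew * Wc))))
      Wc <- Wnew
      if (conv < tol) { ok <- TRUE; break }
    }
    if (ok) { Wrot <- Wc; break }
  }
  if (is.null(Wrot))
    stop("fastICA failed to converge after 5 restarts (tol = ", tol,
         ", max_iter = ", max_iter, "); sources may be Gaussian")

  M <- Z %*% t(Wrot)                       # scores, unit variance
  Wout <- Wrot %*% diag(sqrt(lam), k) %*% t(U)   # k x m
  colnames(Wout) <- colnames(Z0)
  ev <- rowSums(Wout^2) / sum(e$values)    # rank-1 reconstruction shares
  unmixing <- Kw %*% t(Wrot)               # M = Xs %*% unmixing
  new_decomposition("ICA", Wout, M, ev, unmixing,
                    colnames(Z0), s$center, s$scale)
}

#' Canonical orientation and ordering of a decomposition
#'
#' Resolves the sign and order indeterminacy of ICA so that component
#' labels are reproducible: each component is flipped so its largest-|weight|
#' trait loads positively, components are sorted by explained variance
#' (descending), and labels `C1..Ck` are reassigned. Idempotent; leaves a
#' PCA decomposition's order unchanged.
#'
#' @param d a `decomposition`.
#' @return The reoriented `decomposition`.
#' @export
orient_and_order <- function(d) {
  stopifnot(inherits(d, "decomposition"))
  k <- nrow(d$W)
  for (i in seq_len(k)) {
    j <- which.max(abs(d$W[i, ]))
    if (d$W[i, j] < 0) {
      d$W[i, ] <- -d$W[i, ]
      d$M[, i] <- -d$M[, i]
      d$unmixing[, i] <- -d$unmixing[, i]
    }
  }
  ord <- order(d$explained_variance, decreasing = TRUE)
  d$W <- d$W[ord, , drop = FALSE]
  d$M <- d$M[, ord, drop = FALSE]
  d$unmixing <- d$unmixing[, ord, drop = FALSE]
  d$explained_variance <- d$explained_variance[ord]
  d$component_labels <- paste0("C", seq_len(k))
  colnames(d$M) <- d$component_labels
  rownames(d$W) <- d$component_labels
  d
}

#' Amari performance index of a mixing-unmixing product
#'
#' For `P = A %*% unmixing` (true mixing times estimated unmixing), the
#' index is 0 iff `P` is a scaled signed permutation and at most 1;
#' values below 0.05 indicate essentially exact source recovery.
#'
#' @param P square numeric matrix.
#' @return A number in \[0, 1\].
#' @export
amari_index <- function(P) {
  P <- abs(as.matrix(P))
  k <- nrow(P)
  stopifnot(ncol(P) == k, k >= 2)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(sweep(P, 2, apply(P, 2, max), "/")) - 1)
  (r + c) / (2 * k * (k - 1))
}

#' Write decomposition weights and scores as TSV
#' @param d a `decomposition`.
#' @param weights_path,scores_path output paths.
#' @param individual_ids optional ids for the score rows.
#' @return Invisibly, the two paths.
#' @export
write_decomposition <- function(d, weights_path, scores_path,
                                individual_ids = NULL) {
  w <- data.frame(component = d$component_labels, d$W, check.names = FALSE)
  utils::write.table(w, weights_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  m <- data.frame(individual_id = if (is.null(individual_ids))
    seq_len(nrow(d$M)) else individual_ids, d$M, check.names = FALSE)
  utils::write.table(m, scores_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(weights_path, scores_path))
}
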