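# Pedigree kinship. The recursive algorithm processes individuals in
# topological order (parents first):
#   founders:      phi_ii = 1/2, phi between distinct founders = 0
#   non-founder i: phi_ij = (phi_fj + phi_mj)/2  for previously placed j
#                  phi_ii = (1 + phi_fm)/2
# Inbreeding falls out of the recursion (diagonal may exceed 1/2).
# The mixed model downstream uses the additive relationship matrix 2*phi.

#' Kinship coefficient matrix from a pedigree
#'
#' @param ped a [pedigree_table]. Individual ids must be globally unique so
#'   the matrix can be aligned with genotype/phenotype containers.
#' @return A symmetric matrix of kinship coefficients (class
#'   `kinship_matrix`), dimnames = individual ids in pedigree order.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  if (anyDuplicated(ped$individual_id))
    stop("kinship requires globally unique individual ids")
  n <- nrow(ped)
  ord <- pedigree_topo_order(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  phi <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  placed <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {                      # founder
      phi[i, i] <- 0.5
    } else {
      if (length(placed)) {
        v <- 0.5 * (phi[fa[i], placed] + phi[mo[i], placed])
        phi[i, placed] <- v
        phi[placed, i] <- v
      }
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
    }
    placed <- c(placed, i)
  }
  structure(phi, class = c("kinship_matrix", "matrix", "array"))
}

#' Monte-Carlo kinship by gene dropping
#'
#' Every founder receives two unique allele labels; alleles are transmitted
#' Mendelianly down the pedigree. The empirical kinship between i and j is
#' the average, over replicates and over the four allele pairings, of the
#' probability that a random allele from i is identical by descent to a
#' random allele from j. Serves as an independent oracle for
#' [kinship_matrix].
#'
#' @param ped a [pedigree_table].
#' @param n_replicates number of independent gene drops.
#' @param seed integer RNG seed (same seed, same output).
#' @return Symmetric numeric matrix of empirical kinship coefficients.
#' @export
gene_drop_kinship <- function(ped, n_replicates = 1e5, seed = 1) {
  stopifnot(inherits(ped, "pedigree_table"), n_replicates >= 1)
  set.seed(seed)
  n <- nrow(ped)
  R <- as.integer(n_replicates)
  ord <- pedigree_topo_order(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  # allele labels per individual: two R-length integer vectors
  A1 <- matrix(0L, n, R); A2 <- matrix(0L, n, R)
  next_label <- 1L
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[i, ] <- next_label; A2[i, ] <- next_label + 1L
      next_label <- next_label + 2L
    } else {
      pick1 <- stats::runif(R) < 0.5
      A1[i, ] <- ifelse(pick1, A1[fa[i], ], A2[fa[i], ])
      pick2 <- stats::runif(R) < 0.5
      A2[i, ] <- ifelse(pick2, A1[mo[i], ], A2[mo[i], ])
    }
  }
  K <- matrix(0, n, n, dimnames = list(ped$individual_id, ped$individual_id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ibd <- (A1[i, ] == A1[j, ]) + (A1[i, ] == A2[j, ]) +
             (A2[i, ] == A1[j, ]) + (A2[i, ] == A2[j, ])
      if (i == j) ibd <- ibd - 2L   # self-pairings a1==a1, a2==a2 counted above
      k <- if (i == j) 0.5 + mean(ibd) / 4 else mean(ibd) / 4
      K[i, j] <- k; K[j, i] <- k
    }
  }
  K
}

#' Precompute the eigendecomposition of the additive relationship matrix
#'
#' `fit_polygenic` diagonalizes 2*phi once and reuses it for every trait and
#' SNP tested against the same set of individuals.
#'
#' @param K a kinship matrix (from [kinship_matrix]) or any symmetric PSD
#'   matrix of kinship coefficients with dimnames.
#' @return A list of class `kinship_eigen` with `vectors`, `values`, `ids`.
#' @export
kinship_eigen <- function(K) {
  A <- 2 * unclass(K)
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    warning("additive relationship matrix has eigenvalue ", min(e$values))
  structure(list(vectors = e$vectors, values = pmax(e$values, 0),
                 ids = rownames(K)),
            class = "kinship_eigen")
}
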