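# Simulator of family-structured multivariate phenotype studies, shaped
# like a 21-extended-family design (mean pedigree size 19): pedigrees grown
# from founder couples, Mendelian gene dropping of unlinked SNPs, and trait
# matrices built as linear mixtures of latent sources (polygenic,
# SNP-driven, or non-Gaussian environmental) plus measurement noise and
# covariate effects. Everything is seeded and reproducible; this module is
# the ground-truth generator every recovery test in the package relies on.

MALE_PROB <- 0.85 / 1.85   # male:female ratio 0.85

#' Simulate extended pedigrees
#'
#' Families are grown from a founder couple for `n_generations`
#' generations: every couple has a Poisson number of children, and every
#' child in a non-final generation marries a new founder spouse. The
#' Poisson mean is calibrated so the expected family size equals
#' `mean_size`.
#'
#' @param n_families number of independent families.
#' @param mean_size expected number of individuals per family.
#' @param n_generations 2, 3 or 4.
#' @param seed RNG seed.
#' @return A [pedigree_table] with globally unique individual ids.
#' @export
simulate_pedigrees <- function(n_families = 21, mean_size = 19,
                               n_generations = 3, seed = 1) {
  stopifnot(n_families >= 1, n_generations %in% 2:4)
  if (mean_size < n_generations)
    stop("mean_size must be at least n_generations")
  expected_size <- function(lam) {
    ct <- lam; size <- 2
    for (t in 2:n_generations) {
      size <- size + ct + if (t < n_generations) ct else 0  # children + spouses
      ct <- lam * ct
    }
    size
  }
  lam <- stats::uniroot(function(l) expected_size(l) - mean_size,
                        c(1e-6, 50))$root
  set.seed(seed)
  fam <- iid <- fa <- mo <- character(0); sex <- integer(0)
  for (f in seq_len(n_families)) {
    fid <- sprintf("F%02d", f)
    counter <- 0L
    new_id <- function() {
      counter <<- counter + 1L
      sprintf("%s_I%03d", fid, counter)
    }
    add <- function(id, father, mother, s) {
      fam <<- c(fam, fid); iid <<- c(iid, id)
      fa <<- c(fa, father); mo <<- c(mo, mother); sex <<- c(sex, s)
    }
    dad <- new_id(); add(dad, NA, NA, 1L)
    mum <- new_id(); add(mum, NA, NA, 2L)
    couples <- list(c(dad, mum))
    for (t in 2:n_generations) {
      next_couples <- list()
      for (cp in couples) {
        n_kids <- stats::rpois(1, lam)
        for (kk in seq_len(n_kids)) {
          kid <- new_id()
          ks <- if (stats::runif(1) < MALE_PROB) 1L else 2L
          add(kid, cp[1], cp[2], ks)
          if (t < n_generations) {        # marry in a founder spouse
            sp <- new_id()
            add(sp, NA, NA, if (ks == 1L) 2L else 1L)
            next_couples[[length(next_couples) + 1L]] <-
              if (ks == 1L) c(kid, sp) else c(sp, kid)
          }
        }
      }
      couples <- next_couples
      if (!length(couples)) break
    }
  }
  pedigree_table(fam, iid, fa, mo, sex)
}

#' Drop genotypes through a pedigree
#'
#' Founders draw genotypes Binomial(2, maf) per SNP (Hardy-Weinberg);
#' children receive one allele from each parent uniformly at random. SNPs
#' are unlinked. No genotyping error.
#'
#' @param ped a [pedigree_table].
#' @param n_snps number of SNPs.
#' @param mafs minor allele frequencies in (0, 0.5], recycled to `n_snps`.
#' @param seed RNG seed.
#' @param missing_rate optional fraction of cells set to missing (MCAR).
#' @return A [genotype_matrix].
#' @export
drop_genotypes <- function(ped, n_snps, mafs = 0.3, seed = 1,
                           missing_rate = 0) {
  stopifnot(inherits(ped, "pedigree_table"), n_snps >= 1,
            all(mafs > 0), all(mafs <= 0.5),
            missing_rate >= 0, missing_rate < 1)
  mafs <- rep_len(mafs, n_snps)
  set.seed(seed)
  n <- nrow(ped)
  ord <- pedigree_topo_order(ped)
  fa <- match(ped$father_id, ped$individual_id)
  mo <- match(ped$mother_id, ped$individual_id)
  A1 <- A2 <- matrix(0L, n, n_snps)
  for (i in ord) {
    if (is.na(fa[i])) {
      A1[i, ] <- stats::rbinom(n_snps, 1, mafs)
      A2[i, ] <- stats::rbinom(n_snps, 1, mafs)
    } else {
      p1 <- stats::runif(n_snps) < 0.5
      A1[i, ] <- ifelse(p1, A1[fa[i], ], A2[fa[i], ])
      p2 <- stats::runif(n_snps) < 0.5
      A2[i, ] <- ifelse(p2, A1[mo[i], ], A2[mo[i], ])
    }
  }
  vals <- A1 + A2
  if (missing_rate > 0)
    vals[matrix(stats::runif(n * n_snps) < missing_rate, n, n_snps)] <- NA
  chrom <- as.character(1 + (seq_len(n_snps) - 1) %% 22)
  pos_in_chrom <- stats::ave(seq_len(n_snps), chrom, FUN = seq_along)
  markers <- data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
                        chromosome = chrom,
                        position = as.integer(1e5 + pos_in_chrom * 5e4),
                        allele_minor = "A", allele_major = "G",
                        stringsAsFactors = FALSE)
  genotype_matrix(vals, ped$individual_id, markers)
}

#' Ground truth for a simulated phenotype study
#'
#' @param mixing_matrix q x m matrix mixing latent sources into traits.
#' @param source_types character vector of length q; each of `"polygenic"`,
#'   `"snp_driven"`, `"laplace"`, `"uniform"`, `"gaussian"`.
#' @param h2_per_source heritability of each polygenic source (ignored for
#'   other types), in \[0, 1\].
#' @param causal_snp_ids snp_id for each snp_driven source (`NA`
#'   elsewhere).
#' @param snp_var_explained fraction of each snp_driven source's variance
#'   explained by its SNP.
#' @param covariate_effects m x 2 matrix of trait effects of standardized
#'   age and 0/1 sex (male = 1); default none.
#' @param noise_sd standard deviation of the trait-level measurement noise.
#' @param missing_rate MCAR missingness applied by [inject_missing] when
#'   simulating a full study.
#' @param seed RNG seed.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(mixing_matrix, source_types,
                             h2_per_source = rep(0, length(source_types)),
                             causal_snp_ids = rep(NA_character_,
                                                  length(source_types)),
                             snp_var_explained = rep(0, length(source_types)),
                             covariate_effects = NULL,
                             noise_sd = 0.3, missing_rate = 0, seed = 1) {
  mixing_matrix <- as.matrix(mixing_matrix)
  q <- nrow(mixing_matrix)
  types <- c("polygenic", "snp_driven", "laplace", "uniform", "gaussian")
  stopifnot(length(source_types) == q, all(source_types %in% types),
            all(is.finite(mixing_matrix)),
            all(h2_per_source >= 0), all(h2_per_source <= 1),
            all(snp_var_explained >= 0), all(snp_var_explained <= 1),
            missing_rate >= 0, missing_rate < 1, noise_sd >= 0)
  if (any(source_types == "snp_driven" & is.na(causal_snp_ids)))
    stop("snp_driven sources need a causal_snp_id")
  if (!is.null(covariate_effects)) {
    covariate_effects <- as.matrix(covariate_effects)
    stopifnot(nrow(covariate_effects) == ncol(mixing_matrix),
              ncol(covariate_effects) == 2)
  }
  structure(list(mixing_matrix = mixing_matrix, source_types = source_types,
                 h2_per_source = h2_per_source,
                 causal_snp_ids = causal_snp_ids,
                 snp_var_explained = snp_var_explained,
                 covariate_effects = covariate_effects,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = seed),
            class = "simulation_truth")
}

#' @keywords internal
matrix_sqrt <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

#' Simulate trait values as mixtures of latent sources
#'
#' Sources are built per `truth$source_types`, each with unit variance:
#' polygenic sources draw a breeding value with covariance h2 * 2*Phi
#' (block-diagonal by family) plus an independent residual; snp_driven
#' sources mix the standardized causal genotype with noise; laplace /
#' uniform / gaussian sources are i.i.d. draws. Traits are
#' `S %*% mixing_matrix` plus Gaussian measurement noise and covariate
#' effects (age simulated uniform on 1-88 years; sex taken from the
#' pedigree, male coded 1).
#'
#' @param ped a [pedigree_table].
#' @param G a [genotype_matrix] containing any causal SNPs.
#' @param truth a [simulation_truth].
#' @param seed RNG seed (defaults to `truth$seed`).
#' @return A list with `phenotypes` (a [phenotype_matrix] with `age` and
#'   `sex` covariates) and `sources` (the n x q latent source matrix).
#' @export
simulate_phenotypes <- function(ped, G, truth, seed = truth$seed) {
  stopifnot(inherits(ped, "pedigree_table"), inherits(truth, "simulation_truth"))
  A <- truth$mixing_matrix
  q <- nrow(A); m <- ncol(A)
  n <- nrow(ped)
  set.seed(seed)
  S <- matrix(0, n, q)
  phi2 <- NULL
  for (s in seq_len(q)) {
    S[, s] <- switch(
      truth$source_types[s],
      polygenic = {
        if (is.null(phi2)) phi2 <- 2 * unclass(kinship_matrix(ped))
        h2 <- truth$h2_per_source[s]
        b <- numeric(n)
        for (f in unique(ped$family_id)) {
          idx <- which(ped$family_id == f)
          L <- matrix_sqrt(phi2[idx, idx, drop = FALSE])
          b[idx] <- L %*% stats::rnorm(length(idx))
        }
        sqrt(h2) * b + sqrt(1 - h2) * stats::rnorm(n)
      },
      snp_driven = {
        j <- match(truth$causal_snp_ids[s], G$markers$snp_id)
        if (is.na(j)) stop("causal SNP absent: ", truth$causal_snp_ids[s])
        g <- G$values[match(ped$individual_id, G$individual_ids), j]
        if (anyNA(g)) stop("causal SNP has missing genotypes")
        gs <- (g - mean(g)) / stats::sd(g)
        v <- truth$snp_var_explained[s]
        sqrt(v) * gs + sqrt(1 - v) * stats::rnorm(n)
      },
      laplace = (stats::rexp(n) - stats::rexp(n)) / sqrt(2),
      uniform = stats::runif(n, -sqrt(3), sqrt(3)),
      gaussian = stats::rnorm(n))
  }
  X <- S %*% A + truth$noise_sd * matrix(stats::rnorm(n * m), n, m)
  age <- stats::runif(n, 1, 88)
  sex01 <- ifelse(ped$sex == 1L, 1, 0)
  if (!is.null(truth$covariate_effects)) {
    age_std <- (age - mean(age)) / stats::sd(age)
    X <- X + outer(age_std, truth$covariate_effects[, 1]) +
      outer(sex01, truth$covariate_effects[, 2])
  }
  colnames(S) <- paste0("S", seq_len(q))
  ph <- phenotype_matrix(X, sprintf("T%02d", seq_len(m)), ped$individual_id,
                         cbind(age = age, sex = sex01))
  list(phenotypes = ph, sources = S)
}

#' Delete phenotype cells completely at random
#'
#' Guarantees at least one observed cell per row and per column (cells are
#' restored where the draw would empty a line).
#'
#' @param X a [phenotype_matrix].
#' @param rate missing fraction in \[0, 0.5\].
#' @param seed RNG seed.
#' @return A [phenotype_matrix] with `NA` holes.
#' @export
inject_missing <- function(X, rate, seed = 1) {
  stopifnot(inherits(X, "phenotype_matrix"), rate >= 0, rate <= 0.5)
  if (rate == 0) return(X)
  set.seed(seed)
  vals <- X$values
  mask <- matrix(stats::runif(length(vals)) < rate, nrow(vals))
  # never empty a row or a column
  for (i in which(rowSums(!mask) == 0))
    mask[i, sample(ncol(mask), 1)] <- FALSE
  for (j in which(colSums(!mask) == 0))
    mask[sample(nrow(mask), 1), j] <- FALSE
  vals[mask] <- NA
  phenotype_matrix(vals, X$trait_names, X$individual_ids, X$covariates)
}

#' Simulate a complete family study in one call
#'
#' Convenience wrapper used by the pipeline example and the test suite:
#' pedigrees, gene-dropped genotypes, mixed-source phenotypes and (per
#' `truth$missing_rate`) missing cells.
#'
#' @inheritParams simulate_pedigrees
#' @param n_snps number of SNPs to drop.
#' @param mafs minor allele frequencies, recycled.
#' @param truth a [simulation_truth]; its `seed` is ignored in favour of
#'   `seed`.
#' @return A list: `pedigree`, `genotypes`, `phenotypes`, `sources`,
#'   `kinship`, `truth`.
#' @export
simulate_study <- function(truth, n_families = 21, mean_size = 19,
                           n_generations = 3, n_snps = 50, mafs = 0.3,
                           seed = 1) {
  ped <- simulate_pedigrees(n_families, mean_size, n_generations, seed)
  G <- drop_genotypes(ped, n_snps, mafs, seed + 1L)
  sim <- simulate_phenotypes(ped, G, truth, seed + 2L)
  ph <- sim$phenotypes
  if (truth$missing_rate > 0)
    ph <- inject_missing(ph, truth$missing_rate, seed + 3L)
  list(pedigree = ped, genotypes = G, phenotypes = ph,
       sources = sim$sources, kinship = kinship_matrix(ped), truth = truth)
}
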