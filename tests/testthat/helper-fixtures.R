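# Fixture pedigrees with textbook kinship values, and small generators
# shared across test files. Everything is built in code at test time.

ped_nuclear <- function() {
  pedigree_table(rep("F1", 4), c("f", "m", "c1", "c2"),
                 c(NA, NA, "f", "f"), c(NA, NA, "m", "m"),
                 c(1, 2, 1, 2))
}

ped_halfsibs <- function() {
  pedigree_table(rep("F1", 5), c("f", "m1", "m2", "k1", "k2"),
                 c(NA, NA, NA, "f", "f"), c(NA, NA, NA, "m1", "m2"),
                 c(1, 2, 2, 1, 1))
}

# first cousins: two sibs marry unrelated spouses; one child each
ped_cousins <- function() {
  pedigree_table(rep("F1", 8),
                 c("gf", "gm", "s1", "s2", "sp1", "sp2", "c1", "c2"),
                 c(NA, NA, "gf", "gf", NA, NA, "s1", "sp2"),
                 c(NA, NA, "gm", "gm", NA, NA, "sp1", "s2"),
                 c(1, 2, 1, 2, 2, 1, 1, 2))
}

# inbred loop: the two first cousins marry; their child has F = 1/16
ped_inbred <- function() {
  pedigree_table(rep("F1", 9),
                 c("gf", "gm", "s1", "s2", "sp1", "sp2", "c1", "c2", "cc"),
                 c(NA, NA, "gf", "gf", NA, NA, "s1", "sp2", "c1"),
                 c(NA, NA, "gm", "gm", NA, NA, "sp1", "s2", "c2"),
                 c(1, 2, 1, 2, 2, 1, 1, 2, 1))
}

# low-rank trait matrix with optional noise
low_rank_pheno <- function(n, m, r, noise = 0, seed = 1) {
  set.seed(seed)
  Y <- matrix(rnorm(n * r), n, r) %*% matrix(rnorm(r * m), r, m)
  if (noise > 0) Y <- Y + noise * matrix(rnorm(n * m), n, m)
  phenotype_matrix(Y, sprintf("T%02d", seq_len(m)))
}

# non-Gaussian (Laplace) latent factors: identifiable for ICA fixtures
nongaussian_pheno <- function(n, m, q, noise = 0.3, seed = 1) {
  set.seed(seed)
  S <- matrix((rexp(n * q) - rexp(n * q)) / sqrt(2), n, q)
  A <- matrix(runif(q * m, 0.3, 1) * sample(c(-1, 1), q * m, TRUE), q, m)
  Y <- S %*% A + noise * matrix(rnorm(n * m), n, m)
  phenotype_matrix(Y, sprintf("T%02d", seq_len(m)))
}

# tiny PLINK text pair written into dir; returns the two paths
write_toy_plink <- function(dir, ped_lines, map_lines) {
  ped <- file.path(dir, "toy.ped")
  map <- file.path(dir, "toy.map")
  writeLines(ped_lines, ped)
  writeLines(map_lines, map)
  c(ped = ped, map = map)
}

# breeding-value simulator for variance-component tests:
# y = sqrt(h2) * L z + sqrt(1 - h2) * e with L L' = 2 Phi
kinship_chol <- function(K) {
  A <- 2 * unclass(K)
  t(chol(A + 1e-10 * diag(nrow(A))))
}

simulate_polygenic_y <- function(L, h2) {
  n <- nrow(L)
  drop(sqrt(h2) * (L %*% rnorm(n)) + sqrt(1 - h2) * rnorm(n))
}

# small on-disk study for pipeline tests and the reproducibility criterion
make_study_files <- function(dir, seed = 101) {
  A <- rbind(c(1.0, 0.8, 0.9, 0.0, 0.1, 0.0),
             c(0.0, 0.2, 0.1, 1.0, 0.9, 0.8))
  truth <- simulation_truth(A, c("laplace", "snp_driven"),
                            causal_snp_ids = c(NA, "snp0003"),
                            snp_var_explained = c(0, 0.35),
                            noise_sd = 0.3, missing_rate = 0.05)
  sim <- simulate_study(truth, n_families = 5, mean_size = 10,
                        n_snps = 12, mafs = 0.3, seed = seed)
  paths <- list(ped = file.path(dir, "study.ped"),
                map = file.path(dir, "study.map"),
                pheno = file.path(dir, "study_pheno.tsv"))
  write_plink(sim$pedigree, sim$genotypes, paths$ped, paths$map)
  write_phenotypes(sim$phenotypes, paths$pheno)
  paths$traits <- sim$phenotypes$trait_names
  paths
}
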