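toy_qc_fixture <- function() {
  # s1..s4 complete with identical heterozygosity; s5 fully missing;
  # snp4 monomorphic. Defaults must remove exactly s5 and snp4.
  vals <- rbind(s1 = c(0, 1, 2, 0),
                s2 = c(1, 0, 2, 0),
                s3 = c(2, 1, 0, 0),
                s4 = c(1, 2, 0, 0),
                s5 = c(NA, NA, NA, NA))
  markers <- data.frame(snp_id = paste0("snp", 1:4), chromosome = "1",
                        position = 1:4 * 1000L, allele_minor = "A",
                        allele_major = "G", stringsAsFactors = FALSE)
  genotype_matrix(vals, rownames(vals), markers)
}

test_that("maf counts the coded allele over non-missing genotypes", {
  expect_equal(maf(c(0, 0, 1, 2)), 3 / 8)
  expect_equal(maf(c(0, 0, 0)), 0)
  expect_equal(maf(c(2, NA, 0)), 0.5)
  expect_error(maf(c(NA, NA)), "all genotypes missing")
})

test_that("ibs_matrix matches hand-computed sharing", {
  mk <- function(k) data.frame(snp_id = paste0("s", seq_len(k)),
                               chromosome = "1", position = seq_len(k),
                               allele_minor = "A", allele_major = "G")
  G <- genotype_matrix(rbind(a = c(0, 2), b = c(1, 1)), c("a", "b"), mk(2))
  expect_equal(ibs_matrix(G)["a", "b"], 0.5)  # mean(0.5, 0.5)
  G2 <- genotype_matrix(rbind(a = c(0, 0, 0), b = c(2, 2, 2), c = c(0, 0, 0)),
                        c("a", "b", "c"), mk(3))
  ibs <- ibs_matrix(G2)
  expect_equal(ibs["a", "b"], 0)      # maximal difference
  expect_equal(ibs["a", "c"], 1)      # duplicated individual
  expect_true(isSymmetric(ibs))
  expect_equal(unname(diag(ibs)), rep(1, 3))
  # pair with no jointly observed SNP is flagged missing
  G3 <- genotype_matrix(rbind(a = c(0, NA), b = c(NA, 1)), c("a", "b"), mk(2))
  expect_true(is.na(ibs_matrix(G3)["a", "b"]))
})

test_that("heterozygosity outliers agree with brute-force BH", {
  set.seed(7)
  n <- 50; p <- 200
  vals <- matrix(rbinom(n * p, 2, 0.3), n, p)
  vals[1, ] <- rbinom(p, 1, 0.9) * 1   # h ~ 0.9: clear outlier
  ids <- sprintf("s%02d", 1:n)
  mk <- data.frame(snp_id = paste0("m", 1:p), chromosome = "1",
                   position = 1:p, allele_minor = "A", allele_major = "G")
  G <- genotype_matrix(vals, ids, mk)
  flagged <- heterozygosity_outliers(G, fdr = 0.01)
  expect_true("s01" %in% flagged)
  # brute-force BH on the same robust-z p-values
  het <- rowSums(vals == 1) / p
  z <- (het - median(het)) / mad(het)
  pv <- 2 * pnorm(-abs(z))
  ord <- order(pv)
  k <- max(c(0, which(sort(pv) <= 0.01 * seq_len(n) / n)))
  manual <- if (k == 0) character(0) else ids[ord[seq_len(k)]]
  expect_setequal(flagged, manual)
  # invariant to sample order
  perm <- sample(n)
  Gp <- genotype_matrix(vals[perm, ], ids[perm], mk)
  expect_setequal(heterozygosity_outliers(Gp, 0.01), flagged)
  # all-identical heterozygosity: empty with a warning
  Gc <- genotype_matrix(matrix(1, 12, 4), sprintf("c%d", 1:12), mk[1:4, ])
  expect_warning(out <- heterozygosity_outliers(Gc, 0.01), "zero MAD")
  expect_length(out, 0)
})

test_that("apply_qc removes exactly the constructed offenders, in order", {
  res <- apply_qc(toy_qc_fixture())
  expect_equal(res$report$removed_individuals$individual_id, "s5")
  expect_equal(res$report$removed_individuals$reason, "sample_call_rate")
  expect_equal(res$report$removed_markers$snp_id, "snp4")
  expect_equal(res$report$removed_markers$reason, "maf")
  expect_equal(rownames(res$genotypes$values), c("s1", "s2", "s3", "s4"))
  # idempotence
  res2 <- apply_qc(res$genotypes)
  expect_equal(res2$genotypes$values, res$genotypes$values)
  expect_equal(nrow(res2$report$removed_individuals), 0)
  expect_equal(nrow(res2$report$removed_markers), 0)
  # surviving markers satisfy the thresholds
  th <- qc_thresholds()
  expect_true(all(apply(res$genotypes$values, 2, maf) >= th$maf_min))
  expect_true(all(colMeans(!is.na(res$genotypes$values)) >=
                    th$marker_call_rate_min))
})

test_that("extreme permissive thresholds remove nothing", {
  G <- toy_qc_fixture()
  keep_all <- genotype_matrix(G$values[1:4, ], G$individual_ids[1:4],
                              G$markers)
  th <- qc_thresholds(sample_call_rate_min = 0, sample_ibs_max = 1,
                      sample_het_fdr = 1e-12, marker_call_rate_min = 0,
                      maf_min = 0)
  res <- apply_qc(keep_all, th)
  expect_equal(res$genotypes$values, keep_all$values)
  expect_equal(nrow(res$report$removed_individuals), 0)
  expect_equal(nrow(res$report$removed_markers), 0)
})

test_that("of a duplicated pair exactly one member is removed", {
  set.seed(9)
  vals <- matrix(rbinom(6 * 60, 2, 0.3), 6, 60)
  vals[2, ] <- vals[1, ]           # duplicate of s1
  vals[2, 1:3] <- NA               # s2 has the lower call rate
  ids <- paste0("s", 1:6)
  mk <- data.frame(snp_id = paste0("m", 1:60), chromosome = "1",
                   position = 1:60, allele_minor = "A", allele_major = "G")
  res <- apply_qc(genotype_matrix(vals, ids, mk),
                  qc_thresholds(sample_het_fdr = 1e-12))
  ibs_removed <- subset(res$report$removed_individuals, reason == "ibs")
  expect_equal(ibs_removed$individual_id, "s2")
  expect_true("s1" %in% rownames(res$genotypes$values))
})
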