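# Sample- and marker-level genotype QC. Filter order is fixed:
# sample call rate -> sample heterozygosity -> sample IBS -> marker call
# rate -> marker MAF. Marker statistics are computed after sample removal.

#' QC thresholds
#'
#' Defaults follow common array-QC practice (GenABEL-style): samples need a
#' call rate of at least 0.95, pairs sharing IBS above 0.95 are treated as
#' duplicates, heterozygosity outliers are flagged at FDR 1\%, markers need a
#' call rate of at least 0.95 and a minor allele frequency of at least 0.0064.
#'
#' @param sample_call_rate_min,marker_call_rate_min fractions in \[0,1\].
#' @param sample_ibs_max fraction in \[0,1\].
#' @param sample_het_fdr fraction in (0,1).
#' @param maf_min fraction in \[0,0.5\].
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          sample_ibs_max = 0.95,
                          sample_het_fdr = 0.01,
                          marker_call_rate_min = 0.95,
                          maf_min = 0.0064) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            marker_call_rate_min >= 0, marker_call_rate_min <= 1,
            sample_ibs_max >= 0, sample_ibs_max <= 1,
            sample_het_fdr > 0, sample_het_fdr < 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 sample_ibs_max = sample_ibs_max,
                 sample_het_fdr = sample_het_fdr,
                 marker_call_rate_min = marker_call_rate_min,
                 maf_min = maf_min),
            class = "qc_thresholds")
}

#' Minor allele frequency of one additively coded genotype column
#'
#' @param column numeric vector of 0/1/2 genotypes with `NA` for missing.
#' @return `min(p, 1 - p)` where `p` is the coded-allele frequency among
#'   non-missing genotypes.
#' @export
maf <- function(column) {
  ok <- !is.na(column)
  if (!any(ok)) stop("MAF undefined: all genotypes missing")
  p <- sum(column[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

#' Identity-by-state matrix between samples
#'
#' Entry (i, j) is the mean over SNPs non-missing in both samples of
#' `1 - |g_i - g_j| / 2`; a duplicated sample gives 1, maximally different
#' genotypes give 0. Pairs with no jointly observed SNP are `NA`.
#'
#' @param G a [genotype_matrix].
#' @return Symmetric n x n matrix with unit diagonal.
#' @export
ibs_matrix <- function(G) {
  vals <- G$values
  stopifnot(nrow(vals) >= 2, ncol(vals) >= 1)
  obs <- !is.na(vals)
  v0 <- vals; v0[!obs] <- 0
  # sum over shared SNPs of |g_i - g_j| via the 0/1/2 level indicators
  lev <- lapply(0:2, function(g) (v0 == g & obs) * 1)
  n_shared <- obs %*% t(obs)
  absdiff <- matrix(0, nrow(vals), nrow(vals))
  for (a in 0:2) for (b in 0:2) {
    if (a == b) next
    absdiff <- absdiff + abs(a - b) * (lev[[a + 1]] %*% t(lev[[b + 1]]))
  }
  ibs <- 1 - absdiff / (2 * n_shared)
  ibs[n_shared == 0] <- NA
  diag(ibs) <- 1
  dimnames(ibs) <- list(G$individual_ids, G$individual_ids)
  ibs
}

#' Samples with outlying heterozygosity
#'
#' Per-sample heterozygosity (share of heterozygous calls among non-missing
#' genotypes) is converted to a robust z-score (median/MAD), a two-sided
#' normal p-value, and thresholded by Benjamini-Hochberg at the given FDR.
#'
#' @param G a [genotype_matrix].
#' @param fdr false discovery rate in (0,1).
#' @return Character vector of flagged individual ids (possibly empty).
#' @export
heterozygosity_outliers <- function(G, fdr = 0.01) {
  stopifnot(fdr > 0, fdr < 1)
  vals <- G$values
  het <- rowSums(vals == 1, na.rm = TRUE) / rowSums(!is.na(vals))
  s <- stats::mad(het, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    warning("zero MAD of heterozygosity; no outliers flagged")
    return(character(0))
  }
  z <- (het - stats::median(het, na.rm = TRUE)) / s
  p <- 2 * stats::pnorm(-abs(z))
  flag <- !is.na(p) & stats::p.adjust(p, "BH") <= fdr
  G$individual_ids[flag]
}

#' Apply the full QC filter cascade
#'
#' @param G a [genotype_matrix].
#' @param thresholds a [qc_thresholds] object.
#' @return A list with `genotypes` (filtered [genotype_matrix]) and `report`
#'   (class `qc_report`: data.frames `removed_individuals` and
#'   `removed_markers`, each with a `reason` column, plus `counts`).
#' @export
apply_qc <- function(G, thresholds = qc_thresholds()) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  removed_ind <- data.frame(individual_id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  removed_mkr <- data.frame(snp_id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  drop_samples <- function(G, ids, reason) {
    if (!length(ids)) return(G)
    removed_ind <<- rbind(removed_ind,
                          data.frame(individual_id = ids, reason = reason,
                                     stringsAsFactors = FALSE))
    keep <- !(G$individual_ids %in% ids)
    genotype_matrix(G$values[keep, , drop = FALSE],
                    G$individual_ids[keep], G$markers)
  }

  # 1. sample call rate
  cr <- rowMeans(!is.na(G$values))
  G <- drop_samples(G, G$individual_ids[cr < thresholds$sample_call_rate_min],
                    "sample_call_rate")
  if (!nrow(G$values)) stop("QC removed every individual (sample call rate)")

  # 2. sample heterozygosity
  het_ids <- suppressWarnings(
    heterozygosity_outliers(G, thresholds$sample_het_fdr))
  G <- drop_samples(G, het_ids, "heterozygosity")
  if (!nrow(G$values)) stop("QC removed every individual (heterozygosity)")

  # 3. sample IBS: of a flagged pair, drop the member with the lower call rate
  if (nrow(G$values) >= 2) {
    ibs <- ibs_matrix(G)
    cr <- rowMeans(!is.na(G$values))
    drop <- character(0)
    pairs <- which(upper.tri(ibs) & !is.na(ibs) & ibs > thresholds$sample_ibs_max,
                   arr.ind = TRUE)
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        i <- pairs[r, 1]; j <- pairs[r, 2]
        ids <- G$individual_ids[c(i, j)]
        if (any(ids %in% drop)) next
        worse <- if (cr[i] < cr[j]) ids[1] else if (cr[j] < cr[i]) ids[2] else
          max(ids)  # call-rate tie: drop the lexicographically later id
        drop <- c(drop, worse)
      }
    }
    G <- drop_samples(G, drop, "ibs")
  }
  if (!nrow(G$values)) stop("QC removed every individual (IBS)")

  # 4. marker call rate (computed on surviving samples)
  mcr <- colMeans(!is.na(G$values))
  bad_cr <- mcr < thresholds$marker_call_rate_min
  # 5. marker MAF (also on surviving samples; all-missing handled by step 4)
  mafs <- rep(NA_real_, ncol(G$values))
  some <- colSums(!is.na(G$values)) > 0
  mafs[some] <- apply(G$values[, some, drop = FALSE], 2, maf)
  bad_maf <- !bad_cr & (!some | mafs < thresholds$maf_min)
  if (any(bad_cr))
    removed_mkr <- rbind(removed_mkr,
                         data.frame(snp_id = G$markers$snp_id[bad_cr],
                                    reason = "marker_call_rate",
                                    stringsAsFactors = FALSE))
  if (any(bad_maf))
    removed_mkr <- rbind(removed_mkr,
                         data.frame(snp_id = G$markers$snp_id[bad_maf],
                                    reason = "maf", stringsAsFactors = FALSE))
  keep <- !(bad_cr | bad_maf)
  G <- genotype_matrix(G$values[, keep, drop = FALSE], G$individual_ids,
                       G$markers[keep, , drop = FALSE])

  report <- structure(
    list(removed_individuals = removed_ind,
         removed_markers = removed_mkr,
         counts = c(table(removed_ind$reason), table(removed_mkr$reason))),
    class = "qc_report")
  list(genotypes = G, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", nrow(x$removed_individuals), "individuals and",
      nrow(x$removed_markers), "markers removed\n")
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Write a QC report as TSV (individuals then markers, with a `kind` column)
#' @param report a `qc_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_qc_report <- function(report, path) {
  a <- report$removed_individuals
  b <- report$removed_markers
  out <- rbind(
    if (nrow(a)) data.frame(kind = "individual", id = a$individual_id,
                            reason = a$reason) else NULL,
    if (nrow(b)) data.frame(kind = "marker", id = b$snp_id,
                            reason = b$reason) else NULL)
  if (is.null(out)) out <- data.frame(kind = character(), id = character(),
                                      reason = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
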