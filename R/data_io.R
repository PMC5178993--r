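# Readers/writers for every external format the pipeline touches.
# Text PLINK (.ped/.map) only: data are desk-scale and fixtures stay
# human-inspectable. No binary .bed, no VCF, no strand handling.

#' Read text PLINK genotypes (.ped/.map)
#'
#' Recodes genotypes additively against the minor allele computed from the
#' file itself; `0 0` allele pairs become missing. When the two alleles of a
#' SNP have frequency exactly 0.5 the alphabetically first allele is labelled
#' minor, so the coding is deterministic.
#'
#' @param ped_path path to a whitespace-delimited .ped file: FID, IID,
#'   father, mother, sex, phenotype, then two allele columns per SNP.
#' @param map_path path to the matching .map file: chromosome, snp_id,
#'   genetic distance, position.
#' @return A list with components `pedigree` (a [pedigree_table]) and
#'   `genotypes` (a [genotype_matrix]).
#' @export
read_plink <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "snp_id", "cm", "position"),
                           colClasses = c("character", "character", "numeric", "integer"))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in ", map_path)
  n_snps <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_snps
  bad <- which(vapply(toks, length, 1L) != want)
  if (length(bad))
    stop(sprintf("%s line %d: expected %d fields (6 + 2 x %d SNPs), found %d",
                 ped_path, bad[1], want, n_snps, length(toks[[bad[1]]])))
  m <- do.call(rbind, toks)
  fid <- m[, 1]; iid <- m[, 2]
  if (anyDuplicated(paste(fid, iid, sep = "\r")))
    stop("duplicate IID within FID in ", ped_path)
  ped <- pedigree_table(fid, iid, m[, 3], m[, 4], as.integer(m[, 5]))

  a1 <- m[, 6L + 2L * seq_len(n_snps) - 1L, drop = FALSE]
  a2 <- m[, 6L + 2L * seq_len(n_snps), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  half_missing <- xor(is.na(a1), is.na(a2))
  if (any(half_missing)) {
    a1[half_missing] <- NA; a2[half_missing] <- NA
  }
  geno <- matrix(NA_integer_, nrow(m), n_snps)
  allele_minor <- allele_major <- character(n_snps)
  for (j in seq_len(n_snps)) {
    als <- c(a1[, j], a2[, j])
    tab <- sort(table(als))  # ascending count
    obs <- names(tab)
    if (length(obs) > 2)
      stop(sprintf("SNP %s: more than two alleles (%s)",
                   map$snp_id[j], paste(obs, collapse = ", ")))
    if (length(obs) == 0) {           # fully missing marker
      allele_minor[j] <- allele_major[j] <- NA_character_
      next
    }
    if (length(obs) == 1) {            # monomorphic: everyone lacks the
      allele_minor[j] <- NA_character_ # (unobserved) minor allele
      allele_major[j] <- obs
      geno[!is.na(a1[, j]), j] <- 0L
      next
    }
    if (tab[[1]] == tab[[2]]) {        # exact tie: alphabetical rule
      minor <- min(obs); major <- max(obs)
    } else {
      minor <- obs[1]; major <- obs[2]
    }
    allele_minor[j] <- minor; allele_major[j] <- major
    geno[, j] <- (a1[, j] == minor) + (a2[, j] == minor)
  }
  markers <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                        position = map$position, allele_minor = allele_minor,
                        allele_major = allele_major, stringsAsFactors = FALSE)
  list(pedigree = ped, genotypes = genotype_matrix(geno, iid, markers))
}

#' Write text PLINK genotypes (.ped/.map)
#'
#' Inverse of [read_plink]; the round trip reproduces genotype values and
#' marker metadata exactly.
#'
#' @param ped a [pedigree_table] aligned with `G`.
#' @param G a [genotype_matrix].
#' @param ped_path,map_path output paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_plink <- function(ped, G, ped_path, map_path) {
  stopifnot(inherits(ped, "pedigree_table"), inherits(G, "genotype_matrix"))
  vals <- align_rows(G$values, G$individual_ids, ped$individual_id)
  mk <- G$markers
  utils::write.table(
    data.frame(mk$chromosome, mk$snp_id, 0, mk$position),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- nrow(ped)
  allele_txt <- matrix("0", n, 2L * ncol(vals))
  for (j in seq_len(ncol(vals))) {
    g <- vals[, j]
    mi <- mk$allele_minor[j]; ma <- mk$allele_major[j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, mi, ma))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, mi, ma))
    allele_txt[, 2L * j - 1L] <- a1
    allele_txt[, 2L * j] <- a2
  }
  lead <- cbind(ped$family_id, ped$individual_id,
                ifelse(is.na(ped$father_id), "0", ped$father_id),
                ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                ped$sex, 0)
  writeLines(apply(cbind(lead, allele_txt), 1, paste, collapse = " "), ped_path)
  invisible(c(ped_path, map_path))
}

#' Read a pedigree table from delimited text
#'
#' @param path TSV/CSV with header; columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex` (`0` or empty means unknown parent).
#' @param sep field separator, default tab.
#' @return A [pedigree_table].
#' @export
read_pedigree <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pedigree file lacks column(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  pedigree_table(tab$family_id, tab$individual_id, tab$father_id,
                 tab$mother_id, as.integer(tab$sex))
}

#' Write a pedigree table as TSV
#' @param ped a [pedigree_table].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quantitative phenotype table
#'
#' @param path delimited text with a header, an `individual_id` column and a
#'   `family_id` column.
#' @param trait_columns names of the trait columns to extract.
#' @param covariate_columns names of covariate columns (e.g. `age`, `sex`);
#'   may be empty.
#' @param sep field separator, default tab.
#' @param na_strings strings parsed as missing, besides the empty cell.
#' @return A [phenotype_matrix].
#' @export
read_phenotypes <- function(path, trait_columns, covariate_columns = character(),
                            sep = "\t", na_strings = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           na.strings = c(na_strings, ""))
  need <- c("individual_id", trait_columns, covariate_columns)
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(tab), collapse = ", "))
  vals <- as.matrix(tab[, trait_columns, drop = FALSE])
  storage.mode(vals) <- "double"
  cov <- NULL
  if (length(covariate_columns)) {
    cov <- as.matrix(tab[, covariate_columns, drop = FALSE])
    storage.mode(cov) <- "double"
  }
  phenotype_matrix(vals, trait_columns, as.character(tab$individual_id), cov)
}

#' Write a phenotype matrix as TSV
#' @param X a [phenotype_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(X, path) {
  out <- data.frame(individual_id = X$individual_ids,
                    X$values, check.names = FALSE)
  if (!is.null(X$covariates))
    out <- cbind(out, as.data.frame(X$covariates))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association results table
#'
#' Tab-separated, one row per (SNP, metaphenotype) pair, sorted by
#' (chromosome, position, metaphenotype) so output is deterministic.
#'
#' @param results data.frame of class `assoc_result` as returned by [gwas].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_assoc_table <- function(results, path) {
  if (!nrow(results)) stop("no association results to write")
  cols <- c("snp_id", "chromosome", "position", "metaphenotype", "maf",
            "beta", "lrt_stat", "p_raw", "p_adjusted", "significant")
  stopifnot(all(cols %in% names(results)))
  ord <- order(results$chromosome, results$position, results$metaphenotype)
  out <- results[ord, cols]
  num <- vapply(out, is.numeric, TRUE) & names(out) != "position"
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association results table written by [write_assoc_table]
#' @param path input path.
#' @return A data.frame with the same columns.
#' @export
read_assoc_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(snp_id = "character",
                                   chromosome = "character",
                                   metaphenotype = "character"))
}

#' Write a kinship matrix as TSV with an id header row and column
#' @param K kinship matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_kinship <- function(K, path) {
  out <- data.frame(individual_id = rownames(K), unclass(K)[,, drop = FALSE],
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
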