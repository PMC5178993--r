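#' Pedigree table
#'
#' A validated table of individuals with family membership, parent links and
#' sex. This is the sole source of relatedness information in the package:
#' the kinship matrix is computed from it, never from markers.
#'
#' @param family_id character vector of family identifiers.
#' @param individual_id character vector, unique within each family (and, for
#'   use with genotype/phenotype matrices, globally unique).
#' @param father_id,mother_id character vectors; `NA` (or `"0"`) for founders.
#'   Either both parents are missing (founder) or both are present.
#' @param sex integer vector: 1 = male, 2 = female, 0 = unknown.
#'
#' @return An object of class `pedigree_table` (a data.frame).
#' @export
pedigree_table <- function(family_id, individual_id, father_id, mother_id, sex) {
  n <- length(individual_id)
  stopifnot(length(family_id) == n, length(father_id) == n,
            length(mother_id) == n, length(sex) == n)
  norm_id <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & x == "0"] <- NA_character_
    x
  }
  ped <- data.frame(
    family_id     = as.character(family_id),
    individual_id = as.character(individual_id),
    father_id     = norm_id(father_id),
    mother_id     = norm_id(mother_id),
    sex           = as.integer(sex),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree_table", "data.frame")
  validate_pedigree(ped)
  ped
}

#' @keywords internal
validate_pedigree <- function(ped) {
  if (!all(ped$sex %in% c(0L, 1L, 2L)))
    stop("pedigree: sex must be coded 0 (unknown), 1 (male) or 2 (female)")
  dup <- duplicated(paste(ped$family_id, ped$individual_id, sep = "\r"))
  if (any(dup))
    stop("pedigree: duplicate individual_id within family: ",
         paste(unique(ped$individual_id[dup]), collapse = ", "))
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent))
    stop("pedigree: individuals with exactly one known parent: ",
         paste(ped$individual_id[one_parent], collapse = ", "))
  key <- paste(ped$family_id, ped$individual_id, sep = "\r")
  for (col in c("father_id", "mother_id")) {
    p <- ped[[col]]
    bad <- !is.na(p) & !(paste(ped$family_id, p, sep = "\r") %in% key)
    if (any(bad))
      stop("pedigree: unknown ", col, " within family for individual(s): ",
           paste(ped$individual_id[bad], collapse = ", "))
  }
  # acyclicity via Kahn's algorithm doubles as the topological sort
  pedigree_topo_order(ped)
  invisible(ped)
}

#' Topological order of a pedigree (parents before children)
#' @keywords internal
pedigree_topo_order <- function(ped) {
  n <- nrow(ped)
  key <- paste(ped$family_id, ped$individual_id, sep = "\r")
  fa <- match(paste(ped$family_id, ped$father_id, sep = "\r"), key)
  mo <- match(paste(ped$family_id, ped$mother_id, sep = "\r"), key)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  # children lists
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    i <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, i)
    for (ch in kids[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != n)
    stop("pedigree: cycle detected (an individual is its own ancestor)")
  order
}

#' Genotype matrix
#'
#' Individuals by SNPs, additively coded as the count of the minor allele
#' (0, 1, 2) with `NA` for missing genotypes, plus per-marker metadata.
#'
#' @param values integer/numeric matrix, individuals in rows.
#' @param individual_ids character vector, one per row.
#' @param markers data.frame with columns `snp_id`, `chromosome`, `position`,
#'   `allele_minor`, `allele_major`; one row per column of `values`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, individual_ids, markers) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(individual_ids),
            ncol(values) == nrow(markers))
  need <- c("snp_id", "chromosome", "position", "allele_minor", "allele_major")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(markers$snp_id))
    stop("duplicate snp_id in markers")
  if (any(markers$position < 0))
    stop("negative marker position")
  ok <- values[!is.na(values)]
  if (length(ok) && !all(ok %in% c(0, 1, 2)))
    stop("genotype values must be 0, 1, 2 or NA")
  rownames(values) <- individual_ids
  colnames(values) <- markers$snp_id
  structure(list(values = values,
                 individual_ids = as.character(individual_ids),
                 markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Phenotype matrix
#'
#' Individuals by quantitative traits (possibly with missing values), with an
#' optional covariate matrix (e.g. age in years and sex coded 0/1) carried
#' alongside so downstream models can adjust for it.
#'
#' @param values numeric matrix, individuals in rows, traits in columns.
#' @param trait_names character vector of unique column names.
#' @param individual_ids character vector, one per row.
#' @param covariates optional numeric matrix with named columns, same rows.
#' @return An object of class `phenotype_matrix`.
#' @export
phenotype_matrix <- function(values, trait_names = colnames(values),
                             individual_ids = rownames(values),
                             covariates = NULL) {
  values <- as.matrix(values)
  if (is.null(trait_names)) stop("trait_names required")
  if (is.null(individual_ids))
    individual_ids <- as.character(seq_len(nrow(values)))
  stopifnot(length(trait_names) == ncol(values),
            length(individual_ids) == nrow(values))
  if (anyDuplicated(trait_names)) stop("duplicate trait names")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(values))
    if (is.null(colnames(covariates)))
      stop("covariate columns must be named")
  }
  dimnames(values) <- list(individual_ids, trait_names)
  structure(list(values = values,
                 trait_names = as.character(trait_names),
                 individual_ids = as.character(individual_ids),
                 covariates = covariates),
            class = "phenotype_matrix")
}

#' @export
print.phenotype_matrix <- function(x, ...) {
  cat(sprintf("phenotype_matrix: %d individuals x %d traits (%.1f%% missing)%s\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values)),
              if (is.null(x$covariates)) "" else
                sprintf(", covariates: %s",
                        paste(colnames(x$covariates), collapse = ", "))))
  invisible(x)
}

#' Align a genotype or phenotype matrix to a set of individual ids
#' @keywords internal
align_rows <- function(values, ids, want) {
  idx <- match(want, ids)
  if (anyNA(idx))
    stop("individuals absent: ", paste(want[is.na(idx)], collapse = ", "))
  values[idx, , drop = FALSE]
}
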