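# End-to-end orchestration: qc -> impute -> decompose -> orient ->
# heritability -> gwas -> compare/graphs. Every stage writes its artifact
# into the output directory and appends a log line; a manifest of md5
# hashes closes the run. Log lines carry no timestamps so that two runs
# with the same config and seed are bit-identical.

#' Assemble and validate a pipeline configuration
#'
#' @param ped_path,map_path text PLINK genotype files (the .ped file also
#'   carries the pedigree).
#' @param phenotype_path delimited phenotype table.
#' @param trait_columns,covariate_columns column names in the phenotype
#'   table.
#' @param out_dir output directory (created if absent).
#' @param qc a [qc_thresholds] object.
#' @param methods decomposition methods to run: subset of `c("ica", "pca")`.
#' @param k `"auto"` (cross-validated) or a fixed integer.
#' @param k_max largest candidate when `k = "auto"`.
#' @param bpca_q latent dimension for imputation (default m - 1).
#' @param alpha significance level for the Bonferroni-adjusted p-values.
#' @param seed integer master seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ped_path, map_path, phenotype_path,
                            trait_columns, covariate_columns = c("age", "sex"),
                            out_dir, qc = qc_thresholds(),
                            methods = c("ica", "pca"), k = "auto",
                            k_max = NULL, bpca_q = NULL, alpha = 0.05,
                            seed = 1) {
  stopifnot(all(methods %in% c("ica", "pca")), length(methods) >= 1,
            identical(k, "auto") || (is.numeric(k) && k >= 1))
  structure(list(ped_path = ped_path, map_path = map_path,
                 phenotype_path = phenotype_path,
                 trait_columns = trait_columns,
                 covariate_columns = covariate_columns,
                 out_dir = out_dir, qc = qc, methods = methods, k = k,
                 k_max = k_max, bpca_q = bpca_q, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full two-stage metaphenotype pipeline
#'
#' @param config a [pipeline_config].
#' @return Invisibly, the output directory. Artifacts: `qc_report.tsv`,
#'   `phenotypes_imputed.tsv`, per-method `weights_*.tsv` / `scores_*.tsv`
#'   / `heritability_*.tsv` / `assoc_*.tsv`, `kinship.tsv`,
#'   `comparison_ica_pca.tsv` and GraphML graphs when both methods run,
#'   `pipeline.log`, and `manifest.tsv` (md5 of every artifact).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat(sprintf("pipeline start seed=%d\n", config$seed), file = log_path)
  logln <- function(...)
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  plink <- stage("read", read_plink(config$ped_path, config$map_path))
  ped <- plink$pedigree
  X <- stage("read", read_phenotypes(config$phenotype_path,
                                     config$trait_columns,
                                     config$covariate_columns))
  logln("read: %d individuals, %d SNPs, %d traits", nrow(ped),
        ncol(plink$genotypes$values), length(config$trait_columns))

  qcres <- stage("qc", apply_qc(plink$genotypes, config$qc))
  G <- qcres$genotypes
  write_qc_report(qcres$report, file.path(out, "qc_report.tsv"))
  logln("qc: removed %d individuals, %d markers; %d x %d remain",
        nrow(qcres$report$removed_individuals),
        nrow(qcres$report$removed_markers),
        nrow(G$values), ncol(G$values))

  ids <- intersect(G$individual_ids, X$individual_ids)
  if (!all(ids %in% ped$individual_id))
    stop("individuals missing from the pedigree: ",
         paste(setdiff(ids, ped$individual_id), collapse = ", "))
  idx <- match(ids, X$individual_ids)
  X <- phenotype_matrix(X$values[idx, , drop = FALSE], X$trait_names, ids,
                        if (is.null(X$covariates)) NULL else
                          X$covariates[idx, , drop = FALSE])
  G <- genotype_matrix(G$values[match(ids, G$individual_ids), , drop = FALSE],
                       ids, G$markers)
  K <- kinship_matrix(ped)
  K <- structure(unclass(K)[ids, ids],
                 class = c("kinship_matrix", "matrix", "array"))
  write_kinship(K, file.path(out, "kinship.tsv"))
  eig <- kinship_eigen(K)
  logln("align: %d individuals in analysis set", length(ids))

  m <- ncol(X$values)
  model <- stage("impute",
                 fit_bpca(X, q = if (is.null(config$bpca_q)) m - 1L else
                   config$bpca_q, seed = config$seed + 10L))
  Ximp <- stage("impute", impute(X, model))
  write_phenotypes(Ximp, file.path(out, "phenotypes_imputed.tsv"))
  logln("impute: %d cells filled, converged=%s",
        sum(is.na(X$values)), model$converged)

  Xs <- stage("decompose", standardize(Ximp))
  k <- config$k
  if (identical(k, "auto")) {
    k_max <- if (is.null(config$k_max)) min(m - 1L, 10L) else config$k_max
    cv <- stage("decompose", choose_k_cv(Xs, k_max, seed = config$seed + 20L))
    k <- cv$k
    utils::write.table(data.frame(k = seq_along(cv$press_curve),
                                  press = cv$press_curve),
                       file.path(out, "press_curve.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    logln("decompose: cross-validation selected k=%d", k)
  }
  Cmat <- Ximp$covariates
  decomps <- list()
  for (method in config$methods) {
    d <- stage("decompose", if (method == "ica")
      orient_and_order(fastica(Xs, k, seed = config$seed + 30L)) else
        orient_and_order(pca(Xs, k)))
    decomps[[method]] <- d
    write_decomposition(d, file.path(out, sprintf("weights_%s.tsv", method)),
                        file.path(out, sprintf("scores_%s.tsv", method)),
                        ids)
    M <- d$M
    colnames(M) <- d$component_labels
    ht <- stage("heritability", heritability_table(M, Cmat, eig))
    utils::write.table(ht, file.path(out,
                                     sprintf("heritability_%s.tsv", method)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res <- stage("gwas", gwas(M, G, Cmat, eig, alpha = config$alpha))
    write_assoc_table(res, file.path(out, sprintf("assoc_%s.tsv", method)))
    logln("%s: k=%d, %d significant of %d tests", method, k,
          sum(res$significant), nrow(res))
  }

  if (all(c("ica", "pca") %in% names(decomps))) {
    cmp <- stage("compare", match_components(decomps$ica, decomps$pca))
    utils::write.table(cmp, file.path(out, "comparison_ica_pca.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if ("ica" %in% names(decomps)) {
    d <- decomps$ica
    for (lab in d$component_labels)
      write_graphml(build_graph(d, lab, Ximp),
                    file.path(out, sprintf("graph_%s.graphml", lab)))
  }

  files <- setdiff(list.files(out), "manifest.tsv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out, files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}
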