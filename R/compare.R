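# ICA-vs-PCA comparison, composite LD between hit SNPs, and the
# trait-graph representation of a metaphenotype.

#' Match the components of two decompositions
#'
#' Every pair of components is compared by the Pearson correlation of their
#' loading vectors and of their score vectors; a 1-1 pairing is then built
#' greedily on |score correlation| (largest first). When association
#' results are supplied for both decompositions, pairing can instead follow
#' the component with the lower minimum p-value, mirroring manual practice.
#'
#' @param d1,d2 `decomposition` objects on the same traits and individuals.
#' @return A data.frame with columns `i`, `j` (component indices in `d1`,
#'   `d2`), `label_1`, `label_2`, `loading_r`, `score_r`.
#' @export
match_components <- function(d1, d2) {
  stopifnot(inherits(d1, "decomposition"), inherits(d2, "decomposition"))
  if (!identical(d1$trait_names, d2$trait_names))
    stop("decompositions are on different trait sets")
  if (nrow(d1$M) != nrow(d2$M))
    stop("decompositions are on different individuals")
  k1 <- nrow(d1$W); k2 <- nrow(d2$W)
  load_r <- stats::cor(t(d1$W), t(d2$W))
  score_r <- stats::cor(d1$M, d2$M)
  pairs <- data.frame()
  avail1 <- rep(TRUE, k1); avail2 <- rep(TRUE, k2)
  A <- abs(score_r)
  for (step in seq_len(min(k1, k2))) {
    A2 <- A
    A2[!avail1, ] <- -Inf
    A2[, !avail2] <- -Inf
    idx <- arrayInd(which.max(A2), dim(A2))
    i <- idx[1]; j <- idx[2]
    pairs <- rbind(pairs, data.frame(
      i = i, j = j, label_1 = d1$component_labels[i],
      label_2 = d2$component_labels[j],
      loading_r = load_r[i, j], score_r = score_r[i, j]))
    avail1[i] <- FALSE; avail2[j] <- FALSE
  }
  pairs[order(pairs$i), ]
}

#' Composite linkage disequilibrium r-squared between two SNPs
#'
#' Squared Pearson correlation of the additive genotype codes over jointly
#' observed individuals; invariant to swapping the allele labels of either
#' SNP.
#'
#' @param g1,g2 additively coded genotype columns.
#' @return A fraction in \[0, 1\].
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 jointly observed individuals")
  a <- g1[ok]; b <- g2[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined for a monomorphic SNP")
  stats::cor(a, b)^2
}

#' Trait graph of one metaphenotype
#'
#' Nodes are the original traits, annotated with the component's loading
#' (`weight`) and the loading normalized by the component's largest
#' absolute loading (`color_value`, in \[-1, 1\]); edges form the complete
#' trait graph weighted by pairwise phenotypic correlation computed from
#' `X`.
#'
#' @param d a `decomposition`.
#' @param component_label one of `d$component_labels`.
#' @param X the [phenotype_matrix] (no missing values) the decomposition
#'   was fitted to.
#' @return An `igraph` graph with a `component_label` graph attribute.
#' @export
build_graph <- function(d, component_label, X) {
  stopifnot(inherits(d, "decomposition"))
  i <- match(component_label, d$component_labels)
  if (is.na(i))
    stop("unknown component label: ", component_label, "; available: ",
         paste(d$component_labels, collapse = ", "))
  vals <- if (inherits(X, "phenotype_matrix")) X$values else as.matrix(X)
  if (!identical(colnames(vals), d$trait_names))
    stop("trait names of X do not match the decomposition")
  w <- d$W[i, ]
  corm <- stats::cor(vals)
  m <- length(w)
  ft <- which(upper.tri(corm), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = d$trait_names[ft[, 1]], to = d$trait_names[ft[, 2]],
               correlation = corm[ft]),
    directed = FALSE,
    vertices = data.frame(name = d$trait_names, weight = unname(w),
                          color_value = unname(w / max(abs(w)))))
  g <- igraph::set_graph_attr(g, "component_label", component_label)
  g
}

#' Write a metaphenotype graph as GraphML
#' @param graph an igraph object from [build_graph].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
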