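# Information-theoretic characterisation of selected SNPs: main-effect
# mutual information, pairwise interaction information, and the
# synergy/redundancy entropy web. Plug-in (maximum-likelihood) estimates in
# bits, without small-sample bias correction.

.entropy_bits <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log2(p[p > 0]))
}

#' Mutual information between two discrete variables (bits)
#'
#' Plug-in empirical estimate `sum p(x, y) log2(p(x, y) / (p(x) p(y)))`, with
#' `0 log 0 = 0`. Always non-negative and symmetric.
#'
#' @param x,y discrete vectors of equal length.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  ind <- outer(px, py)
  keep <- joint > 0
  sum(joint[keep] * log2(joint[keep] / ind[keep]))
}

#' Interaction information of two predictors and an outcome (bits)
#'
#' `I(A; B; Y) = I(A, B; Y) - I(A; Y) - I(B; Y)`: positive values indicate
#' synergy (the pair carries more information about `Y` than its parts),
#' negative values redundancy. Symmetric in `A` and `B`.
#'
#' @param a,b,y discrete vectors of equal length.
#' @return Interaction information in bits.
#' @export
interaction_information <- function(a, b, y) {
  if (length(a) != length(b) || length(a) != length(y))
    stop("a, b and y must have equal length")
  ab <- paste(a, b, sep = ":")
  mutual_information(ab, y) - mutual_information(a, y) -
    mutual_information(b, y)
}

#' Entropy web of a SNP subset
#'
#' Builds the complete graph over the selected SNPs: node values are the
#' phenotype entropy explained by each SNP alone, `100 * I(SNP; Y) / H(Y)`,
#' and edge values the pairwise interaction information
#' `100 * I(A; B; Y) / H(Y)`, both as percentages of the phenotype entropy
#' (set `normalize = FALSE` for raw bits). Positive edges are labelled
#' synergy, negative edges redundancy.
#'
#' @param data a `snp_data` object.
#' @param snp_subset indices or ids of the SNPs to include.
#' @param normalize divide by the phenotype entropy and express as percent
#'   (default `TRUE`).
#' @return An object of class `entropy_web` with `nodes` and `edges`
#'   data.frames and the phenotype entropy `h_y` (bits).
#' @export
build_entropy_web <- function(data, snp_subset, normalize = TRUE) {
  stopifnot(inherits(data, "snp_data"), length(snp_subset) >= 1)
  if (is.character(snp_subset)) snp_subset <- match(snp_subset, data$snp_ids)
  y <- data$phenotype
  hy <- .entropy_bits(y)
  if (hy == 0) stop("phenotype entropy is zero: only one class present")
  scale <- if (normalize) 100 / hy else 1
  ids <- data$snp_ids[snp_subset]
  g <- data$genotypes[, snp_subset, drop = FALSE]
  nodes <- data.frame(
    snp_id = ids,
    value = vapply(seq_along(snp_subset),
                   function(j) scale * mutual_information(g[, j], y), 0),
    stringsAsFactors = FALSE)
  pairs <- if (length(snp_subset) > 1) utils::combn(length(snp_subset), 2)
           else matrix(nrow = 2, ncol = 0)
  edges <- data.frame(
    from = ids[pairs[1, ]], to = ids[pairs[2, ]],
    value = apply(pairs, 2, function(ij)
      scale * interaction_information(g[, ij[1]], g[, ij[2]], y)),
    stringsAsFactors = FALSE)
  if (nrow(edges)) {
    edges$value <- as.numeric(edges$value)
    edges$sign <- ifelse(edges$value >= 0, "synergy", "redundancy")
  } else edges$sign <- character(0)
  structure(list(nodes = nodes, edges = edges, h_y = hy,
                 normalized = normalize),
            class = "entropy_web")
}

#' @export
print.entropy_web <- function(x, ...) {
  unit <- if (x$normalized) "% of phenotype entropy" else "bits"
  cat(sprintf("entropy web: %d SNPs, %d pairs (values in %s; H(Y) = %.3f bits)\n",
              nrow(x$nodes), nrow(x$edges), unit, x$h_y))
  cat("nodes:\n"); print(x$nodes, row.names = FALSE)
  if (nrow(x$edges)) { cat("edges:\n"); print(x$edges, row.names = FALSE) }
  invisible(x)
}

#' Convert an entropy web to an igraph graph
#'
#' Node attribute `value` and edge attributes `value`/`sign` carry the
#' (normalised) information measures.
#'
#' @param web an `entropy_web`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(web) {
  stopifnot(inherits(web, "entropy_web"))
  igraph::graph_from_data_frame(web$edges, directed = FALSE,
                                vertices = web$nodes)
}

#' Write an entropy web in GML graph-exchange format
#'
#' @param web an `entropy_web`.
#' @param path output file.
#' @export
write_entropy_web <- function(web, path) {
  igraph::write_graph(as_igraph(web), path, format = "gml")
  invisible(path)
}
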