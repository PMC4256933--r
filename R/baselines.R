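# Marginal-effects baseline: per-SNP Pearson chi-square test on the 2 x 3
# phenotype-by-genotype table with Bonferroni correction.

#' Chi-square test of marginal genotype effects for one SNP
#'
#' Pearson chi-square on the 2 x 3 phenotype-by-genotype contingency table
#' (2 degrees of freedom when all three genotype categories are usable).
#' Genotype categories whose expected count falls below 1 are collapsed into
#' the adjacent category, reducing the degrees of freedom accordingly; no
#' continuity correction is applied. A monomorphic SNP yields statistic 0,
#' p = 1, and a warning.
#'
#' @param data a `snp_data` object (or genotype matrix with `phenotype`
#'   passed separately).
#' @param snp_index column index or SNP id.
#' @param phenotype binary vector, required when `data` is a plain matrix.
#' @return A one-row data.frame: `snp_id`, `statistic`, `df`, `p_value`.
#' @export
chi2_marginal <- function(data, snp_index, phenotype = NULL) {
  if (inherits(data, "snp_data")) {
    g <- data$genotypes[, snp_index]
    y <- data$phenotype
    id <- if (is.character(snp_index)) snp_index else data$snp_ids[snp_index]
  } else {
    g <- as.matrix(data)[, snp_index]
    y <- phenotype
    id <- as.character(snp_index)
  }
  if (length(unique(y)) < 2) stop("both phenotype classes must be present")
  counts <- rbind(tabulate(g[y == 1] + 1L, 3L), tabulate(g[y == 0] + 1L, 3L))
  res <- .chi2_table(counts)
  data.frame(snp_id = id, statistic = res$statistic, df = res$df,
             p_value = res$p_value, stringsAsFactors = FALSE)
}

.chi2_table <- function(counts) {
  # drop genotype categories absent from the data entirely
  counts <- counts[, colSums(counts) > 0, drop = FALSE]
  if (ncol(counts) < 2) {
    warning("monomorphic SNP: statistic set to 0, p = 1")
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  repeat {
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (all(expected >= 1) || ncol(counts) == 2) break
    j <- which(apply(expected < 1, 2, any))[1]
    nb <- if (j == ncol(counts)) j - 1L else j + 1L
    counts[, nb] <- counts[, nb] + counts[, j]
    counts <- counts[, -j, drop = FALSE]
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- (ncol(counts) - 1L) * (nrow(counts) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Chi-square scan over all SNPs with Bonferroni calls
#'
#' @param data a `snp_data` object.
#' @param alpha family-wise significance level (default 0.05); the per-test
#'   threshold is `alpha / p` for `p` SNPs.
#' @return A data.frame with one row per SNP: `snp_id`, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
chi2_scan <- function(data, alpha = 0.05) {
  stopifnot(inherits(data, "snp_data"))
  p <- ncol(data$genotypes)
  y <- data$phenotype
  rows <- lapply(seq_len(p), function(j) {
    counts <- rbind(tabulate(data$genotypes[y == 1, j] + 1L, 3L),
                    tabulate(data$genotypes[y == 0, j] + 1L, 3L))
    .chi2_table(counts)
  })
  out <- data.frame(snp_id = data$snp_ids,
                    statistic = vapply(rows, `[[`, 0, "statistic"),
                    df = vapply(rows, `[[`, 0L, "df"),
                    p_value = vapply(rows, `[[`, 0, "p_value"),
                    stringsAsFactors = FALSE)
  out$significant <- bonferroni_calls(out$p_value, alpha)
  out
}

#' Bonferroni-corrected significance calls
#'
#' @param p_values numeric vector of p-values.
#' @param alpha family-wise level in `(0, 1)`.
#' @return Logical vector: `p < alpha / length(p_values)`.
#' @export
bonferroni_calls <- function(p_values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  p_values < alpha / length(p_values)
}
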