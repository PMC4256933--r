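# File formats: tab-separated genotype matrices and the PLINK additive
# (.raw-style) text dialect, plus JSON run manifests.

#' Write a SNP dataset to disk
#'
#' `format = "tsv"` writes a tab-separated matrix with a header of SNP ids
#' plus a final `phenotype` column (0/1). `format = "raw"` writes the PLINK
#' additive dialect: `FID IID PHENOTYPE` columns (phenotype coded 1 =
#' control, 2 = case, as PLINK does) followed by one 0/1/2 column per SNP.
#' With `sidecar = TRUE` a JSON file `<path>.json` records the simulation
#' parameters, seed and causal positions when present.
#'
#' @param data a `snp_data` object.
#' @param path output file.
#' @param format `"tsv"` or `"raw"`.
#' @param sidecar write the JSON sidecar (default `TRUE` for simulated data).
#' @export
write_genotypes <- function(data, path, format = c("tsv", "raw"),
                            sidecar = !is.null(data$sim)) {
  stopifnot(inherits(data, "snp_data"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- as.data.frame(data$genotypes)
    df$phenotype <- data$phenotype
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(FID = sprintf("F%d", seq_along(data$phenotype)),
                     IID = sprintf("I%d", seq_along(data$phenotype)),
                     PHENOTYPE = data$phenotype + 1L)
    df <- cbind(df, as.data.frame(data$genotypes))
    write.table(df, path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  if (sidecar) {
    man <- list(format = format, n = length(data$phenotype),
                p = ncol(data$genotypes),
                causal_idx = data$causal_idx,
                sim = data$sim[setdiff(names(data$sim), "penetrance")],
                penetrance = if (!is.null(data$sim$penetrance))
                  unclass(as.matrix(data$sim$penetrance)))
    jsonlite::write_json(man, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' Read a genotype file
#'
#' Accepts the two formats written by [write_genotypes()]; with
#' `format = "auto"` the dialect is detected from the header. Validation
#' errors name the offending row and column. If a JSON sidecar written by
#' [write_genotypes()] exists, causal positions are restored from it.
#'
#' @param path input file.
#' @param format `"auto"`, `"tsv"` or `"raw"`.
#' @return A `snp_data` object.
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  if (format == "auto")
    format <- if (identical(header[1:2], c("FID", "IID"))) "raw" else "tsv"
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    if (!"phenotype" %in% names(df))
      stop("tsv genotype file is missing the phenotype column")
    y <- df$phenotype
    g <- as.matrix(df[setdiff(names(df), "phenotype")])
  } else {
    df <- read.table(path, header = TRUE, check.names = FALSE)
    meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                      names(df))
    if (!"PHENOTYPE" %in% meta)
      stop("raw genotype file is missing the PHENOTYPE column")
    y <- df$PHENOTYPE
    if (all(y %in% c(1, 2))) y <- y - 1L  # PLINK 1/2 coding
    g <- as.matrix(df[setdiff(names(df), meta)])
  }
  if (!all(y %in% c(0, 1)))
    stop("phenotype values must be 0/1 (or PLINK 1/2)")
  snp_data(g, y)
}

#' Write a machine-readable run manifest
#'
#' @param path output JSON file.
#' @param config named list of configuration values.
#' @param seed master seed.
#' @param extra optional named list appended verbatim.
#' @export
write_manifest <- function(path, config, seed, extra = NULL) {
  man <- c(list(package = "epibnn",
                version = as.character(utils::packageVersion("epibnn")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC",
                                   "%Y-%m-%dT%H:%M:%SZ"),
                seed = seed, config = config), extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
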