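# Case-control simulators: two-locus relative-risk models (additive,
# threshold, epistatic) and purely epistatic penetrance tables with
# controlled broad-sense heritability and flat marginal penetrance.

GENO_A <- c("AA", "Aa", "aa")
GENO_B <- c("BB", "Bb", "bb")

#' Two-locus relative-risk table
#'
#' Relative risk of disease for each combination of genotypes at two
#' biallelic loci (rows: locus A genotypes AA/Aa/aa; columns: locus B
#' genotypes BB/Bb/bb), with baseline risk `eta` and effect size `theta`:
#'
#' * `additive`: `eta * (1 + theta * (mA + mB))` where `mA`, `mB` are the
#'   minor-allele counts;
#' * `threshold`: `eta * (1 + theta)` whenever both loci carry at least one
#'   minor allele, `eta` otherwise;
#' * `epistatic`: `eta * (1 + 4 theta)` for AA/bb and aa/BB,
#'   `eta * (1 + 2 theta)` for Aa/Bb, `eta` otherwise.
#'
#' @param model `"additive"`, `"threshold"` or `"epistatic"`.
#' @param eta baseline risk (> 0, default 1).
#' @param theta effect size (>= 0).
#' @return A 3 x 3 numeric matrix with genotype dimnames.
#' @export
risk_table <- function(model = c("additive", "threshold", "epistatic"),
                       eta = 1, theta = 0) {
  model <- match.arg(model)
  stopifnot(eta > 0, theta >= 0)
  m <- outer(0:2, 0:2, function(ma, mb) switch(model,
    additive  = eta * (1 + theta * (ma + mb)),
    threshold = ifelse(ma >= 1 & mb >= 1, eta * (1 + theta), eta),
    epistatic = ifelse((ma == 0 & mb == 2) | (ma == 2 & mb == 0),
                       eta * (1 + 4 * theta),
                       ifelse(ma == 1 & mb == 1, eta * (1 + 2 * theta), eta))))
  dimnames(m) <- list(GENO_A, GENO_B)
  m
}

#' Hardy-Weinberg genotype frequencies
#'
#' @param maf minor allele frequency in `(0, 0.5]`.
#' @return Probabilities of carrying 0, 1, 2 copies of the minor allele:
#'   `((1-q)^2, 2q(1-q), q^2)`.
#' @export
genotype_frequencies_hwe <- function(maf) {
  if (!is.numeric(maf) || maf <= 0 || maf > 0.5)
    stop("maf must be in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Purely epistatic penetrance table
#'
#' Random constrained search for a 3 x 3 table of absolute disease
#' penetrances whose two single-locus marginal penetrances are constant
#' across genotypes (no marginal effects, so the causal pair acts only
#' through its interaction) and whose broad-sense heritability
#' `h2 = sum_g P(g) (f_g - K)^2 / (K (1 - K))`, with prevalence
#' `K = sum_g P(g) f_g` and `P(g)` the Hardy-Weinberg genotype-pair
#' probabilities, matches the target. The search samples a random table,
#' projects it onto the zero-marginal-effect subspace (HWE-weighted row and
#' column means removed), rescales the deviations to hit the target
#' heritability, and rejects tables with entries outside `[0, 1]`.
#'
#' @param h2 target heritability in `[0, 0.5]`.
#' @param maf minor allele frequency of both causal loci.
#' @param prevalence_range interval from which the prevalence `K` is drawn
#'   (default `c(0.1, 0.4)`).
#' @param max_tries rejection-sampling budget (default 10000).
#' @return A 3 x 3 penetrance matrix with attributes `h2`, `maf`,
#'   `prevalence`.
#' @export
pure_epistatic_table <- function(h2, maf, prevalence_range = c(0.1, 0.4),
                                 max_tries = 10000) {
  stopifnot(h2 >= 0, h2 <= 0.5)
  pa <- genotype_frequencies_hwe(maf)
  pg <- outer(pa, pa)
  if (h2 == 0) {
    k <- mean(prevalence_range)
    f <- matrix(k, 3, 3, dimnames = list(GENO_A, GENO_B))
    attr(f, "h2") <- 0; attr(f, "maf") <- maf; attr(f, "prevalence") <- k
    return(f)
  }
  for (try in seq_len(max_tries)) {
    k <- runif(1, prevalence_range[1], prevalence_range[2])
    # temper deviations in rare genotype cells (random exponent per try):
    # low-probability corners otherwise explode after variance rescaling
    # at small MAF, because they barely contribute to the HWE-weighted
    # variance yet must stay inside [0, 1]
    d0 <- matrix(rnorm(9), 3, 3) * pg^runif(1, 0, 0.7)
    # remove HWE-weighted column means (per row), then row means (per
    # column); one pass of each makes both weighted marginals exactly zero
    d1 <- d0 - drop(d0 %*% pa)
    d2 <- d1 - rep(drop(pa %*% d1), each = 3)
    v <- sum(pg * d2^2)
    if (v < 1e-12) next
    f <- k + sqrt(h2 * k * (1 - k) / v) * d2
    if (all(f >= 0 & f <= 1)) {
      dimnames(f) <- list(GENO_A, GENO_B)
      attr(f, "h2") <- h2; attr(f, "maf") <- maf; attr(f, "prevalence") <- k
      return(f)
    }
  }
  stop(sprintf(paste0("no feasible penetrance table found for h2 = %g, ",
                      "maf = %g within %d tries; try a wider prevalence ",
                      "range or smaller h2"), h2, maf, max_tries))
}

#' Realized heritability of a penetrance table
#'
#' @param f 3 x 3 penetrance matrix.
#' @param maf minor allele frequency of both loci.
#' @return Scalar `sum_g P(g) (f_g - K)^2 / (K (1 - K))`.
#' @export
table_heritability <- function(f, maf) {
  pa <- genotype_frequencies_hwe(maf)
  pg <- outer(pa, pa)
  k <- sum(pg * f)
  sum(pg * (f - k)^2) / (k * (1 - k))
}

#' Simulate a case-control SNP dataset
#'
#' Draws the two causal-locus genotype pairs retrospectively: case genotypes
#' with probability proportional to `P(g) * risk(g)` and control genotypes
#' proportional to `P(g)` for the relative-risk models (the rare-disease
#' approximation, under which the baseline `eta` cancels), or proportional to
#' `P(g) * f(g)` and `P(g) * (1 - f(g))` for a purely epistatic penetrance
#' table. Background SNPs are independent Hardy-Weinberg draws with per-SNP
#' MAFs uniform on `background_maf`. All SNP columns are then shuffled and
#' the causal positions recorded.
#'
#' @param model `"additive"`, `"threshold"`, `"epistatic"` or
#'   `"pure_epistatic"`.
#' @param theta effect size for the relative-risk models.
#' @param maf minor allele frequency of the causal loci.
#' @param h2 heritability for `model = "pure_epistatic"`.
#' @param eta baseline risk (cancels under retrospective sampling).
#' @param n_cases,n_controls sample sizes (defaults 1000 each).
#' @param n_background number of non-causal SNPs (default 998).
#' @param background_maf range of background MAFs (default `c(0.05, 0.5)`).
#' @param penetrance optional pre-built penetrance/risk table overriding
#'   `model`/`theta`/`h2`.
#' @param seed integer seed.
#' @return An object of class `snp_data`: integer genotype matrix (rows:
#'   cases then controls), binary `phenotype`, `snp_ids`, logical
#'   `causal_mask`, `causal_idx`, and a `sim` record of the generating
#'   parameters.
#' @export
simulate_case_control <- function(model = c("additive", "threshold",
                                            "epistatic", "pure_epistatic"),
                                  theta = NULL, maf, h2 = NULL, eta = 1,
                                  n_cases = 1000, n_controls = 1000,
                                  n_background = 998,
                                  background_maf = c(0.05, 0.5),
                                  penetrance = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_cases >= 1, n_controls >= 1, n_background >= 0)
  if (!is.null(seed)) set.seed(seed)
  pa <- genotype_frequencies_hwe(maf)
  pg <- outer(pa, pa)
  if (is.null(penetrance)) {
    penetrance <- if (model == "pure_epistatic") {
      if (is.null(h2)) stop("h2 is required for the pure_epistatic model")
      pure_epistatic_table(h2, maf)
    } else {
      if (is.null(theta)) stop("theta is required for this model")
      risk_table(model, eta, theta)
    }
  }
  is_penetrance <- model == "pure_epistatic"
  p_case <- pg * penetrance
  p_ctrl <- if (is_penetrance) pg * (1 - penetrance) else pg
  p_case <- p_case / sum(p_case)
  p_ctrl <- p_ctrl / sum(p_ctrl)

  draw_pairs <- function(n, pr) {
    cell <- sample.int(9L, n, replace = TRUE, prob = as.numeric(pr))
    cbind((cell - 1L) %% 3L,   # locus A minor-allele count (row index)
          (cell - 1L) %/% 3L)  # locus B
  }
  causal <- rbind(draw_pairs(n_cases, p_case), draw_pairs(n_controls, p_ctrl))
  n <- n_cases + n_controls
  p_total <- 2L + n_background
  geno <- matrix(0L, n, p_total)
  pos <- sample.int(p_total, 2L)
  geno[, pos] <- causal
  if (n_background > 0) {
    bg_maf <- runif(n_background, background_maf[1], background_maf[2])
    bg_idx <- setdiff(seq_len(p_total), pos)
    geno[, bg_idx] <- rbinom(n * n_background, 2L, rep(bg_maf, each = n))
  }
  snp_ids <- sprintf("SNP%04d", seq_len(p_total))
  colnames(geno) <- snp_ids
  causal_mask <- seq_len(p_total) %in% pos
  structure(list(genotypes = geno,
                 phenotype = rep(c(1L, 0L), c(n_cases, n_controls)),
                 covariates = NULL,
                 snp_ids = snp_ids,
                 causal_mask = causal_mask,
                 causal_idx = sort(pos),
                 sim = list(model = model, theta = theta, maf = maf, h2 = h2,
                            eta = eta, n_cases = n_cases,
                            n_controls = n_controls,
                            n_background = n_background,
                            background_maf = background_maf,
                            penetrance = penetrance, seed = seed)),
            class = "snp_data")
}

#' Construct a SNP dataset object
#'
#' @param genotypes n x p matrix of minor-allele counts in `{0, 1, 2}`.
#' @param phenotype binary vector (1 = case).
#' @param covariates optional numeric matrix.
#' @param snp_ids SNP identifiers (default: genotype column names).
#' @param causal_mask optional logical truth labels.
#' @return An object of class `snp_data`.
#' @export
snp_data <- function(genotypes, phenotype, covariates = NULL, snp_ids = NULL,
                     causal_mask = NULL) {
  genotypes <- as.matrix(genotypes)
  bad <- which(!(genotypes %in% c(0, 1, 2)))
  if (length(bad)) {
    r <- (bad[1] - 1) %% nrow(genotypes) + 1
    cc <- (bad[1] - 1) %/% nrow(genotypes) + 1
    stop(sprintf("invalid genotype value %s at row %d, column %d (%s)",
                 format(genotypes[bad[1]]), r, cc,
                 colnames(genotypes)[cc] %||% paste0("column ", cc)))
  }
  storage.mode(genotypes) <- "integer"
  phenotype <- as.integer(phenotype)
  stopifnot(length(phenotype) == nrow(genotypes),
            all(phenotype %in% c(0L, 1L)))
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- sprintf("SNP%04d", seq_len(ncol(genotypes)))
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  colnames(genotypes) <- snp_ids
  if (!is.null(causal_mask)) stopifnot(length(causal_mask) == ncol(genotypes))
  structure(list(genotypes = genotypes, phenotype = phenotype,
                 covariates = covariates, snp_ids = snp_ids,
                 causal_mask = causal_mask,
                 causal_idx = if (!is.null(causal_mask)) which(causal_mask),
                 sim = NULL),
            class = "snp_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.snp_data <- function(x, ...) {
  cat(sprintf("snp_data: %d subjects (%d cases / %d controls), %d SNPs\n",
              nrow(x$genotypes), sum(x$phenotype == 1),
              sum(x$phenotype == 0), ncol(x$genotypes)))
  if (!is.null(x$sim))
    cat(sprintf("  simulated: %s model%s, maf %g; causal SNPs at %s\n",
                x$sim$model,
                if (!is.null(x$sim$theta)) sprintf(", theta %g", x$sim$theta)
                else if (!is.null(x$sim$h2)) sprintf(", h2 %g", x$sim$h2)
                else "",
                x$sim$maf, paste(x$causal_idx, collapse = ", ")))
  invisible(x)
}
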