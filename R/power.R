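# Power / false-positive-rate experiment harness: simulate replicate
# datasets for one grid cell, run the BNN + ARD pipeline (and optional
# baselines), and summarise detection of the causal pair.

#' Deterministic per-replicate seed
#'
#' Derives a reproducible 31-bit seed from the master seed, the cell
#' coordinates and the replicate index, so grid cells can be run
#' independently and in any order.
#'
#' @param master master seed (integer).
#' @param cell_id character cell identifier.
#' @param replicate replicate number.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
replicate_seed <- function(master, cell_id, replicate) {
  m <- 2147483647
  s <- as.double(master) %% m
  for (ch in utf8ToInt(paste0(cell_id, "#", replicate)))
    s <- (s * 69069 + ch) %% m
  as.integer(s + 1)
}

#' Run one power-study cell
#'
#' Simulates `replicates` datasets for one combination of genetic model,
#' effect size / heritability and MAF, fits the BNN to each, applies the ARD
#' test, and estimates power as the fraction of replicates in which *both*
#' causal SNPs are called significant, and the false-positive rate as the
#' mean fraction of non-causal SNPs called significant. Binomial standard
#' errors accompany both estimates. A replicate whose sampler fails is
#' logged, excluded, and counted in `n_failed`.
#'
#' @param model,theta,maf,h2 passed to [simulate_case_control()].
#' @param replicates number of replicate datasets (default 10).
#' @param n_cases,n_controls,n_background design sizes.
#' @param cutoff ARD significance cutoff (default 0.6).
#' @param config a [sampler_config()] for the BNN fits.
#' @param hidden hidden units (default 5).
#' @param ard_hyper,output_hyper prior hyperparameters, see [bnn()].
#' @param baselines character vector; include `"chi2"` to also score the
#'   Bonferroni-corrected chi-square scan.
#' @param seed master seed for the cell.
#' @param keep_probs retain each replicate's relevance probabilities and
#'   causal mask (needed for [roc_sweep()]).
#' @param verbose print per-replicate progress.
#' @return An object of class `power_cell`.
#' @export
run_power_cell <- function(model, theta = NULL, maf, h2 = NULL,
                           replicates = 10, n_cases = 1000,
                           n_controls = 1000, n_background = 998,
                           cutoff = 0.6, config = sampler_config(),
                           hidden = 5, ard_hyper = c(5, 2),
                           output_hyper = c(0.1, 0.1),
                           baselines = character(), seed = 1,
                           keep_probs = FALSE, verbose = FALSE) {
  if (!is.null(theta) && is.na(theta)) theta <- NULL
  if (!is.null(h2) && is.na(h2)) h2 <- NULL
  cell_id <- paste(model, theta %||% "", maf, h2 %||% "", sep = "|")
  both <- logical(0); fpr <- numeric(0); chi_both <- logical(0)
  probs <- list(); truths <- list()
  n_failed <- 0L
  for (r in seq_len(replicates)) {
    rs <- replicate_seed(seed, cell_id, r)
    d <- simulate_case_control(model = model, theta = theta, maf = maf,
                               h2 = h2, n_cases = n_cases,
                               n_controls = n_controls,
                               n_background = n_background, seed = rs)
    fit <- tryCatch(
      bnn(d, hidden = hidden, ard_hyper = ard_hyper,
          output_hyper = output_hyper, config = config, seed = rs + 1L),
      error = function(e) {
        message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(fit)) { n_failed <- n_failed + 1L; next }
    rep <- ard_test(fit, cutoff = cutoff)
    causal <- d$causal_mask
    both <- c(both, all(rep$significant[causal]))
    fpr <- c(fpr, mean(rep$significant[!causal]))
    if ("chi2" %in% baselines) {
      sc <- chi2_scan(d)
      chi_both <- c(chi_both, all(sc$significant[causal]))
    }
    if (keep_probs) {
      probs[[length(probs) + 1L]] <- rep$relevance_prob
      truths[[length(truths) + 1L]] <- causal
    }
    if (verbose)
      message(sprintf("cell %s replicate %d: both causal detected = %s, fpr = %.4f",
                      cell_id, r, both[length(both)], fpr[length(fpr)]))
  }
  n_ok <- length(both)
  power <- mean(both)
  fpr_mean <- mean(fpr)
  structure(list(
    cell = list(model = model, theta = theta, maf = maf, h2 = h2,
                n_cases = n_cases, n_controls = n_controls,
                n_background = n_background, cutoff = cutoff),
    power = power,
    power_se = if (n_ok) sqrt(power * (1 - power) / n_ok) else NA_real_,
    fpr = fpr_mean,
    fpr_se = if (n_ok > 1) sd(fpr) / sqrt(n_ok) else NA_real_,
    fpr_per_replicate = fpr,
    chi2_power = if ("chi2" %in% baselines) mean(chi_both) else NULL,
    n_replicates = n_ok, n_failed = n_failed,
    probs = if (keep_probs) probs, truths = if (keep_probs) truths,
    seed = seed), class = "power_cell")
}

#' @export
print.power_cell <- function(x, ...) {
  with(x$cell, cat(sprintf(
    "power cell: %s model%s, maf %g%s; %d cases / %d controls, %d background SNPs\n",
    model, if (!is.null(theta)) sprintf(", theta %g", theta) else "",
    maf, if (!is.null(h2)) sprintf(", h2 %g", h2) else "",
    n_cases, n_controls, n_background)))
  cat(sprintf("  power %.3f (se %.3f), fpr %.4f (se %.4f), %d replicates, %d failed\n",
              x$power, x$power_se, x$fpr, x$fpr_se, x$n_replicates,
              x$n_failed))
  if (!is.null(x$chi2_power))
    cat(sprintf("  chi-square (Bonferroni) power %.3f\n", x$chi2_power))
  invisible(x)
}

#' Run a grid of power-study cells
#'
#' @param grid data.frame with columns `model`, `maf` and, per model,
#'   `theta` and/or `h2`.
#' @param ... passed to [run_power_cell()].
#' @return A data.frame with one row per cell: the cell coordinates, power,
#'   false-positive rate, their standard errors, replicate counts, and chi2
#'   power when requested.
#' @export
power_experiment <- function(grid, ...) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- run_power_cell(model = grid$model[i],
                           theta = if ("theta" %in% names(grid))
                             grid$theta[i],
                           maf = grid$maf[i],
                           h2 = if ("h2" %in% names(grid)) grid$h2[i],
                           ...)
    data.frame(model = grid$model[i],
               theta = if ("theta" %in% names(grid)) grid$theta[i]
                       else NA_real_,
               maf = grid$maf[i],
               h2 = if ("h2" %in% names(grid)) grid$h2[i] else NA_real_,
               power = cell$power, power_se = cell$power_se,
               fpr = cell$fpr, fpr_se = cell$fpr_se,
               n_replicates = cell$n_replicates, n_failed = cell$n_failed,
               chi2_power = cell$chi2_power %||% NA_real_)
  })
  do.call(rbind, rows)
}
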