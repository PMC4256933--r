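# User-facing model fit: bnn() and its methods.

#' Fit a Bayesian neural network to case-control genotype data
#'
#' Fits a one-hidden-layer neural network with logistic hidden units and a
#' two-unit softmax output by Hamiltonian Monte Carlo, interleaving one HMC
#' trajectory with one conjugate Gibbs sweep of the prior variances per
#' iteration. Each SNP's hidden-layer weights form one ARD group with its own
#' Inverse-Gamma-distributed variance; the posterior of these group variances
#' carries the evidence for each SNP's relevance (see [ard_test()]).
#'
#' Genotypes enter as raw minor-allele counts 0/1/2 (one input column per
#' SNP). Covariate columns, if supplied, are appended as extra inputs whose
#' hidden-layer weights share a single Gaussian prior group; covariates are
#' excluded from the ARD relevance test.
#'
#' @param x an n x p genotype matrix with entries in `{0, 1, 2}`, or a
#'   `snp_data` object from [simulate_case_control()] / [read_genotypes()]
#'   (in which case `y` and `covariates` are taken from it).
#' @param y binary phenotype vector (1 = case, 0 = control).
#' @param covariates optional n x q numeric matrix of subject-level
#'   covariates.
#' @param hidden number of hidden units (default 5).
#' @param ard_hyper Inverse-Gamma `c(alpha0, beta0)` for the ARD variances
#'   (default `c(5, 2)`).
#' @param output_hyper Inverse-Gamma `c(alpha0, beta0)` for the shared
#'   output-weight variance (default `c(0.1, 0.1)`).
#' @param bias_variance fixed Gaussian prior variance of all biases
#'   (default 100).
#' @param config a [sampler_config()]; defaults to the package's standard
#'   settings (`step_size = 0.05`, `leapfrog_steps = 15`,
#'   `momentum_persistence = 0.75`, `iterations = 5000`, 25 burn-in and 100
#'   kept draws).
#' @param standardize if `TRUE`, centre and scale input columns before
#'   fitting (default `FALSE`: raw allele counts).
#' @param seed integer seed for the chain; overrides `config$seed`.
#' @param verbose print progress messages.
#' @return An object of class `bnn`: posterior draws of all weights and group
#'   variances (burn-in plus kept, with metadata separating them), the
#'   sampler configuration, acceptance rate, and the data used.
#' @seealso [ard_test()], [sampler_config()], [simulate_case_control()]
#' @examples
#' d <- simulate_case_control(model = "additive", theta = 2, maf = 0.3,
#'                            n_cases = 120, n_controls = 120,
#'                            n_background = 8, seed = 1)
#' cfg <- sampler_config(iterations = 250, burn_in = 5, kept = 20, seed = 1)
#' fit <- bnn(d, config = cfg)
#' fit
#' @export
bnn <- function(x, y = NULL, covariates = NULL, hidden = 5,
                ard_hyper = c(5, 2), output_hyper = c(0.1, 0.1),
                bias_variance = 100, config = sampler_config(),
                standardize = FALSE, seed = NULL, verbose = FALSE) {
  if (inherits(x, "snp_data")) {
    if (is.null(y)) y <- x$phenotype
    if (is.null(covariates)) covariates <- x$covariates
    x <- x$genotypes
  }
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("SNP%04d", seq_len(ncol(x)))
  snp_ids <- colnames(x)
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("phenotype length does not match the number of genotype rows")
  if (!all(y %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2)
    stop("degenerate phenotype: both cases and controls are required")
  if (!all(x %in% c(0, 1, 2)))
    stop("genotypes must be minor-allele counts in {0, 1, 2}")
  storage.mode(x) <- "double"
  p_snp <- ncol(x)
  q <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == nrow(x))
    q <- ncol(covariates)
  }
  xin <- if (q > 0) cbind(x, covariates) else x
  scaling <- NULL
  if (standardize) {
    xin <- scale(xin)
    scaling <- list(center = attr(xin, "scaled:center"),
                    scale = attr(xin, "scaled:scale"))
    xin <- as.matrix(xin)
  }
  if (!is.null(seed)) config$seed <- seed
  t0 <- proc.time()[["elapsed"]]
  chain <- run_bnn_chain(xin, y, p_snp, q, config, hidden = hidden,
                         ard_hyper = ard_hyper, output_hyper = output_hyper,
                         bias_variance = bias_variance, verbose = verbose)
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(
    par_draws = chain$par_draws,
    ard_draws = chain$ard_draws,
    out_draws = chain$out_draws,
    cov_draws = chain$cov_draws,
    lp_trace = chain$lp_trace,
    acceptance_rate = chain$acceptance_rate,
    step_size_used = chain$step_size_used,
    shape = bnn_shape(p_snp + q, hidden),
    p_snp = p_snp, n_covariates = q,
    snp_ids = snp_ids,
    prior = list(ard_hyper = ard_hyper, output_hyper = output_hyper,
                 bias_variance = bias_variance),
    config = config,
    seed = config$seed,
    standardize = standardize, scaling = scaling,
    x = x, covariates = covariates, y = y,
    elapsed = elapsed,
    call = match.call()), class = "bnn")
}

# indices of the kept (post-burn-in) recorded draws
kept_idx <- function(object) object$config$burn_in + seq_len(object$config$kept)

#' @export
print.bnn <- function(x, ...) {
  cat("Bayesian neural network fit\n")
  cat(sprintf("  %d SNPs%s, %d subjects (%d cases / %d controls)\n",
              x$p_snp,
              if (x$n_covariates > 0)
                sprintf(" + %d covariate(s)", x$n_covariates) else "",
              length(x$y), sum(x$y == 1), sum(x$y == 0)))
  cat(sprintf("  hidden units: %d; ARD prior IG(%g, %g); output prior IG(%g, %g)\n",
              x$shape$h, x$prior$ard_hyper[1], x$prior$ard_hyper[2],
              x$prior$output_hyper[1], x$prior$output_hyper[2]))
  cat(sprintf("  HMC: step %g, %d leapfrog steps, persistence %g, %d iterations\n",
              x$config$step_size, x$config$leapfrog_steps,
              x$config$momentum_persistence, x$config$iterations))
  cat(sprintf("  draws: %d burn-in + %d kept (thinning %d); acceptance rate %.2f\n",
              x$config$burn_in, x$config$kept, x$config$thinning,
              x$acceptance_rate))
  if (isTRUE(x$config$adapt_step_size) &&
      !identical(x$step_size_used, x$config$step_size))
    cat(sprintf("  step size adapted during burn-in: %.4g\n",
                x$step_size_used))
  invisible(x)
}

#' @export
summary.bnn <- function(object, cutoff = 0.6, top = 10, ...) {
  rep <- ard_test(object, cutoff = cutoff)
  ord <- order(rep$relevance_prob, decreasing = TRUE)
  structure(list(fit = object, report = rep,
                 top = head(rep[ord, , drop = FALSE], top),
                 cutoff = cutoff), class = "summary.bnn")
}

#' @export
print.summary.bnn <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\nTop SNPs by posterior relevance probability (cutoff %.2f):\n",
              x$cutoff))
  print(x$top, row.names = FALSE)
  cat(sprintf("%d of %d SNPs called significant\n",
              sum(x$report$significant), nrow(x$report)))
  invisible(x)
}

#' Posterior-mean network weights
#'
#' @param object a fitted [bnn()] model.
#' @param ... unused.
#' @return A [bnn_state()] whose entries are posterior means over the kept
#'   draws.
#' @export
coef.bnn <- function(object, ...) {
  pm <- colMeans(object$par_draws[kept_idx(object), , drop = FALSE])
  unpack_state(pm, object$shape$p, object$shape$h)
}

#' Posterior predictive case probabilities
#'
#' Averages the forward pass over the kept posterior draws.
#'
#' @param object a fitted [bnn()] model.
#' @param newx genotype matrix (defaults to the training genotypes).
#' @param newcovariates covariate matrix matching the fit.
#' @param type `"response"` for probabilities, `"class"` for 0/1 calls at 0.5.
#' @param ... unused.
#' @export
predict.bnn <- function(object, newx = NULL, newcovariates = NULL,
                        type = c("response", "class"), ...) {
  type <- match.arg(type)
  if (is.null(newx)) {
    newx <- object$x
    newcovariates <- object$covariates
  }
  newx <- as.matrix(newx)
  xin <- if (object$n_covariates > 0) {
    stopifnot(!is.null(newcovariates))
    cbind(newx, as.matrix(newcovariates))
  } else newx
  if (!is.null(object$scaling))
    xin <- sweep(sweep(xin, 2, object$scaling$center), 2,
                 object$scaling$scale, "/")
  xin <- .as_input_matrix(xin, object$shape$p)
  ki <- kept_idx(object)
  probs <- rowMeans(vapply(ki, function(i) {
    st <- unpack_state(object$par_draws[i, ], object$shape$p, object$shape$h)
    bnn_forward(st, xin)
  }, numeric(nrow(xin))))
  if (type == "class") as.integer(probs > 0.5) else probs
}

#' @export
fitted.bnn <- function(object, ...) predict.bnn(object)

#' @rdname residuals.bnn
#' @export
residuals.bnn <- function(object, ...) object$y - fitted.bnn(object)

#' Residuals of a fitted Bayesian neural network
#'
#' Response residuals: observed case indicator minus posterior predictive
#' case probability.
#'
#' @param object a fitted [bnn()] model.
#' @param ... unused.
#' @name residuals.bnn
NULL

#' Posterior predictive phenotype simulation
#'
#' Draws binary phenotypes from the posterior predictive distribution: for
#' each simulation a kept posterior draw is selected at random and phenotypes
#' are Bernoulli draws from that network's case probabilities.
#'
#' @param object a fitted [bnn()] model.
#' @param nsim number of simulated phenotype vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns, one simulated phenotype vector
#'   each.
#' @export
simulate.bnn <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ki <- kept_idx(object)
  xin <- if (object$n_covariates > 0) cbind(object$x, object$covariates)
         else object$x
  if (!is.null(object$scaling))
    xin <- sweep(sweep(xin, 2, object$scaling$center), 2,
                 object$scaling$scale, "/")
  out <- vapply(seq_len(nsim), function(s) {
    i <- sample(ki, 1)
    st <- unpack_state(object$par_draws[i, ], object$shape$p, object$shape$h)
    as.numeric(rbinom(nrow(xin), 1, bnn_forward(st, xin)))
  }, numeric(nrow(object$x)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Plot method for fitted Bayesian neural networks
#'
#' `type = "relevance"` plots the per-SNP posterior relevance probabilities
#' with the significance threshold implied by `cutoff`; `type = "trace"`
#' plots the recorded log-posterior trace.
#'
#' @param x a fitted [bnn()] model.
#' @param type plot type.
#' @param cutoff ARD cutoff used to draw the threshold line (default 0.6).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bnn <- function(x, type = c("relevance", "trace"), cutoff = 0.6, ...) {
  type <- match.arg(type)
  if (type == "trace") {
    graphics::plot(x$lp_trace, type = "l", xlab = "recorded draw",
                   ylab = "log posterior", ...)
    graphics::abline(v = x$config$burn_in + 0.5, lty = 2)
  } else {
    rep <- ard_test(x, cutoff = cutoff)
    graphics::plot(seq_len(nrow(rep)), rep$relevance_prob, pch = 16,
                   cex = 0.6, xlab = "SNP index",
                   ylab = expression(Pr(mu[j] > mu[null])),
                   ylim = c(0, 1), ...)
    graphics::abline(h = cutoff, lty = 2)
    graphics::points(which(rep$significant),
                     rep$relevance_prob[rep$significant], pch = 16,
                     cex = 0.8, col = 2)
  }
  invisible(x)
}

#' Persist posterior draws as a columnar text archive
#'
#' One row per recorded draw: draw index, burn-in flag, log posterior, the
#' group variances, then the flattened network weights.
#'
#' @param object a fitted [bnn()] model.
#' @param path output file (tab-separated).
#' @export
write_posterior <- function(object, path) {
  n_rec <- nrow(object$par_draws)
  df <- data.frame(draw = seq_len(n_rec),
                   burn_in = seq_len(n_rec) <= object$config$burn_in,
                   log_post = object$lp_trace,
                   output_variance = object$out_draws)
  ard <- object$ard_draws
  colnames(ard) <- paste0("sigma2_", object$snp_ids)
  par <- object$par_draws
  colnames(par) <- paste0("w", seq_len(ncol(par)))
  write.table(cbind(df, ard, par), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
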