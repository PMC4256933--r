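# Hamiltonian Monte Carlo over the network weights, interleaved with
# conjugate Gibbs updates of the ARD / output-layer variances.

#' Symplectic leapfrog integrator
#'
#' Standard leapfrog with half-step momentum updates at both ends, integrating
#' Hamiltonian dynamics for the potential `U = -log_target`. `grad_fn` must
#' return the gradient of the *log target* (not of `U`). The map is
#' deterministic, time-reversible and volume-preserving.
#'
#' @param position,momentum numeric vectors of equal length.
#' @param step_size positive step size.
#' @param n_steps number of leapfrog steps; `0` returns the inputs unchanged.
#' @param grad_fn function(position) -> gradient of the log target density.
#' @return List with elements `position`, `momentum`, and `ok` (`FALSE` if a
#'   non-finite gradient or state was encountered, in which case the caller
#'   should reject the trajectory).
#' @export
leapfrog <- function(position, momentum, step_size, n_steps, grad_fn) {
  stopifnot(step_size > 0, n_steps >= 0)
  if (n_steps == 0)
    return(list(position = position, momentum = momentum, ok = TRUE))
  g <- grad_fn(position)
  if (!all(is.finite(g)))
    return(list(position = position, momentum = momentum, ok = FALSE))
  momentum <- momentum + 0.5 * step_size * g
  for (s in seq_len(n_steps)) {
    position <- position + step_size * momentum
    g <- grad_fn(position)
    if (!all(is.finite(g)) || !all(is.finite(position)))
      return(list(position = position, momentum = momentum, ok = FALSE))
    momentum <- momentum + (if (s < n_steps) step_size else 0.5 * step_size) * g
  }
  list(position = position, momentum = momentum, ok = TRUE)
}

#' One HMC update with partial momentum refreshment
#'
#' Refreshes the momentum as `alpha * momentum + sqrt(1 - alpha^2) * z` with
#' `z` standard normal, runs a leapfrog trajectory, and applies a Metropolis
#' accept/reject step on the Hamiltonian `-log_post + ||momentum||^2 / 2`.
#' On rejection the momentum is negated, which keeps the persistent-momentum
#' chain reversible.
#'
#' @param position current position.
#' @param momentum current momentum (same length).
#' @param log_post_fn function(position) -> log target density (up to a
#'   constant).
#' @param grad_fn function(position) -> gradient of the log target.
#' @param step_size,n_steps leapfrog settings.
#' @param alpha momentum persistence in `[0, 1)`; `0` gives full refreshment.
#' @param lp_current optional cached `log_post_fn(position)`.
#' @return List with `position`, `momentum`, `accepted`, `log_post`.
#' @export
hmc_update <- function(position, momentum, log_post_fn, grad_fn,
                       step_size, n_steps, alpha = 0,
                       lp_current = NULL) {
  stopifnot(alpha >= 0, alpha < 1)
  d <- length(position)
  momentum <- alpha * momentum + sqrt(1 - alpha^2) * rnorm(d)
  if (is.null(lp_current)) lp_current <- log_post_fn(position)
  prop <- leapfrog(position, momentum, step_size, n_steps, grad_fn)
  accepted <- FALSE
  accept_prob <- 0
  if (prop$ok) {
    lp_prop <- log_post_fn(prop$position)
    h0 <- -lp_current + 0.5 * sum(momentum^2)
    h1 <- -lp_prop + 0.5 * sum(prop$momentum^2)
    if (is.finite(h1)) accept_prob <- min(1, exp(h0 - h1))
    if (is.finite(h1) && runif(1) < exp(h0 - h1)) {
      accepted <- TRUE
      position <- prop$position
      momentum <- prop$momentum
      lp_current <- lp_prop
    }
  }
  if (!accepted) momentum <- -momentum
  list(position = position, momentum = momentum, accepted = accepted,
       log_post = lp_current, accept_prob = accept_prob)
}

#' Conjugate Gibbs update of the ARD and output-layer variances
#'
#' With zero-mean Gaussian weights and an Inverse-Gamma(alpha0, beta0) prior,
#' each group variance has full conditional
#' `IG(alpha0 + m/2, beta0 + SS/2)` where `m` is the number of weights in the
#' group and `SS` their sum of squares. SNP groups are the `h` hidden-layer
#' weights of one input column; covariate hidden weights form one shared
#' group; all output weights form the output group. Biases keep their fixed
#' variance.
#'
#' @param state a [bnn_state()].
#' @param prior a [bnn_prior()].
#' @param n_covariates number of trailing input columns that are covariates.
#' @return A new [bnn_prior()] with freshly drawn variances.
#' @export
gibbs_update_variances <- function(state, prior, n_covariates = 0) {
  stopifnot(inherits(state, "bnn_state"), inherits(prior, "bnn_prior"))
  q <- as.integer(n_covariates)
  p_snp <- state$shape$p - q
  h <- state$shape$h
  w <- state$hidden_weights  # h x p
  ss_in <- colSums(w^2)
  ard <- rinvgamma(p_snp,
                   shape = prior$ard_hyper[1] + h / 2,
                   rate = prior$ard_hyper[2] + ss_in[seq_len(p_snp)] / 2)
  covv <- NULL
  if (q > 0) {
    ss_cov <- sum(ss_in[p_snp + seq_len(q)])
    covv <- rinvgamma(1, shape = prior$ard_hyper[1] + q * h / 2,
                      rate = prior$ard_hyper[2] + ss_cov / 2)
  }
  outv <- rinvgamma(1,
                    shape = prior$output_hyper[1] + length(state$output_weights) / 2,
                    rate = prior$output_hyper[2] + sum(state$output_weights^2) / 2)
  bnn_prior(ard_variances = ard, output_variance = outv,
            ard_hyper = prior$ard_hyper, output_hyper = prior$output_hyper,
            bias_variance = prior$bias_variance, covariate_variance = covv)
}

rinvgamma <- function(n, shape, rate) 1 / rgamma(n, shape = shape, rate = rate)

# Fast in-loop version of the Gibbs sweep, working on the flat parameter
# vector. Returns list(ard, covv, outv).
.gibbs_flat <- function(par, p_snp, q, h, ard_hyper, output_hyper) {
  p <- p_snp + q
  ph <- p * h
  whm <- matrix(par[seq_len(ph)], p, h)   # p x h
  ss_in <- rowSums(whm^2)
  ard <- rinvgamma(p_snp, shape = ard_hyper[1] + h / 2,
                   rate = ard_hyper[2] + ss_in[seq_len(p_snp)] / 2)
  covv <- NULL
  if (q > 0)
    covv <- rinvgamma(1, shape = ard_hyper[1] + q * h / 2,
                      rate = ard_hyper[2] + sum(ss_in[p_snp + seq_len(q)]) / 2)
  wo <- par[ph + h + seq_len(2 * h)]
  outv <- rinvgamma(1, shape = output_hyper[1] + h,
                    rate = output_hyper[2] + sum(wo^2) / 2)
  list(ard = ard, covv = covv, outv = outv)
}

#' Sampler configuration
#'
#' @param step_size leapfrog step size (default 0.05).
#' @param leapfrog_steps leapfrog steps per trajectory (default 15).
#' @param momentum_persistence partial momentum refreshment coefficient in
#'   `[0, 1)` (default 0.75).
#' @param iterations total HMC iterations `T` (default 5000). Recorded draws
#'   are obtained by thinning: every `floor(T / (burn_in + kept))`-th
#'   iteration is stored.
#' @param burn_in recorded draws discarded before inference (default 25).
#' @param kept recorded draws used for inference (default 100).
#' @param adapt_step_size if `TRUE` (default), tune the step size by
#'   dual averaging during the burn-in iterations, targeting
#'   `adapt_target` Metropolis acceptance, and freeze it afterwards; the
#'   kept draws always come from a fixed-step-size chain. `step_size` is the
#'   initial value. The leapfrog integrator is only stable up to a
#'   curvature-dependent step size, so the workable value shrinks with the
#'   sample size; adaptation finds it automatically.
#' @param adapt_target target acceptance rate for adaptation (default 0.8).
#' @param seed integer RNG seed, or `NULL` to leave the RNG state alone.
#' @return An object of class `bnn_sampler_config`.
#' @export
sampler_config <- function(step_size = 0.05, leapfrog_steps = 15,
                           momentum_persistence = 0.75, iterations = 5000,
                           burn_in = 25, kept = 100, adapt_step_size = TRUE,
                           adapt_target = 0.8, seed = NULL) {
  stopifnot(step_size > 0, leapfrog_steps >= 1,
            momentum_persistence >= 0, momentum_persistence < 1,
            iterations >= 1, burn_in >= 0, kept >= 1,
            adapt_target > 0, adapt_target < 1)
  thin <- floor(iterations / (burn_in + kept))
  if (thin < 1)
    stop("iterations must be at least burn_in + kept")
  structure(list(step_size = step_size, leapfrog_steps = leapfrog_steps,
                 momentum_persistence = momentum_persistence,
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), kept = as.integer(kept),
                 adapt_step_size = adapt_step_size,
                 adapt_target = adapt_target,
                 thinning = as.integer(thin), seed = seed),
            class = "bnn_sampler_config")
}

# Core chain: alternates one HMC trajectory and one Gibbs sweep of the
# variances per iteration. x is the full input matrix (SNPs then covariates).
run_bnn_chain <- function(x, y, p_snp, q, config,
                          hidden = 5, ard_hyper = c(5, 2),
                          output_hyper = c(0.1, 0.1), bias_variance = 100,
                          init_weight_sd = 0.01, verbose = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(x)
  p <- p_snp + q
  h <- as.integer(hidden)
  d <- p * h + h + 2 * h + 2
  ptr <- bnn_model_ptr(x, as.numeric(y), h)

  # initial state: small Gaussian weights; variances at the prior mean when it
  # exists (alpha0 > 1), otherwise at beta0/alpha0
  par <- rnorm(d, 0, init_weight_sd)
  prior_mean <- function(hy) if (hy[1] > 1) hy[2] / (hy[1] - 1) else hy[2] / hy[1]
  ard <- rep(prior_mean(ard_hyper), p_snp)
  covv <- if (q > 0) prior_mean(ard_hyper) else NULL
  outv <- prior_mean(output_hyper)

  build_pv <- function(ard, covv, outv) {
    v_in <- if (q > 0) c(ard, rep(covv, q)) else ard
    c(rep(v_in, h), rep(bias_variance, h), rep(outv, 2 * h),
      rep(bias_variance, 2))
  }
  pv <- build_pv(ard, covv, outv)
  grad_fn <- function(pos) bnn_grad_ptr(ptr, pos, pv)
  lp_fn <- function(pos) sum(bnn_logpost_ptr(ptr, pos, pv))

  n_rec <- config$burn_in + config$kept
  thin <- config$thinning
  total_iter <- thin * n_rec
  par_draws <- matrix(NA_real_, n_rec, d)
  ard_draws <- matrix(NA_real_, n_rec, p_snp)
  out_draws <- numeric(n_rec)
  cov_draws <- if (q > 0) numeric(n_rec) else NULL
  lp_trace <- numeric(n_rec)

  momentum <- rnorm(d)
  lp_cur <- lp_fn(par)
  n_accept <- 0L
  rec <- 0L
  # dual-averaging step-size adaptation (burn-in iterations only)
  eps <- config$step_size
  n_warm <- if (isTRUE(config$adapt_step_size)) config$burn_in * thin else 0L
  da <- list(mu = log(10 * eps), log_eps_bar = log(eps), h_bar = 0,
             gamma = 0.05, t0 = 10, kappa = 0.75, m = 0L)
  for (it in seq_len(total_iter)) {
    st <- hmc_update(par, momentum, lp_fn, grad_fn,
                     step_size = eps,
                     n_steps = config$leapfrog_steps,
                     alpha = config$momentum_persistence,
                     lp_current = lp_cur)
    par <- st$position
    momentum <- st$momentum
    lp_cur <- st$log_post
    if (st$accepted) n_accept <- n_accept + 1L
    if (it <= n_warm) {
      da$m <- da$m + 1L
      w <- 1 / (da$m + da$t0)
      da$h_bar <- (1 - w) * da$h_bar + w * (config$adapt_target - st$accept_prob)
      log_eps <- da$mu - sqrt(da$m) / da$gamma * da$h_bar
      da$log_eps_bar <- da$m^(-da$kappa) * log_eps +
        (1 - da$m^(-da$kappa)) * da$log_eps_bar
      eps <- exp(log_eps)
      if (it == n_warm) eps <- exp(da$log_eps_bar)
    }

    g <- .gibbs_flat(par, p_snp, q, h, ard_hyper, output_hyper)
    ard <- g$ard; covv <- g$covv; outv <- g$outv
    pv_new <- build_pv(ard, covv, outv)
    # only the prior part of the cached log posterior changes with the
    # variances; update it without another forward pass
    lp_cur <- lp_cur +
      sum(dnorm(par, 0, sqrt(pv_new), log = TRUE)) -
      sum(dnorm(par, 0, sqrt(pv), log = TRUE))
    pv <- pv_new

    if (it %% thin == 0L) {
      rec <- rec + 1L
      par_draws[rec, ] <- par
      ard_draws[rec, ] <- ard
      out_draws[rec] <- outv
      if (q > 0) cov_draws[rec] <- covv
      lp_trace[rec] <- lp_cur
      if (verbose && rec %% 25L == 0L)
        message(sprintf("recorded %d/%d draws (acceptance %.2f)", rec, n_rec,
                        n_accept / it))
    }
  }
  list(par_draws = par_draws, ard_draws = ard_draws, out_draws = out_draws,
       cov_draws = cov_draws, lp_trace = lp_trace,
       acceptance_rate = n_accept / total_iter,
       step_size_used = eps,
       iterations_run = total_iter)
}
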