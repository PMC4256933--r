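# Shared fixtures: small random states, datasets and cached fits.

rand_state <- function(p, h, sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bnn_state(hidden_weights = matrix(rnorm(h * p, 0, sd), h, p),
            hidden_biases = rnorm(h, 0, sd),
            output_weights = matrix(rnorm(2 * h, 0, sd), 2, h),
            output_biases = rnorm(2, 0, sd))
}

zero_state <- function(p, h) {
  bnn_state(matrix(0, h, p), rep(0, h), matrix(0, 2, h), rep(0, 2))
}

rand_prior <- function(p_snp, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bnn_prior(ard_variances = runif(p_snp, 0.2, 2), output_variance = 0.7)
}

toy_genotypes <- function(n, p, seed = 1) {
  set.seed(seed)
  x <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  storage.mode(x) <- "double"
  x
}

# a small fitted model shared across test files (computed lazily once)
.fit_cache <- new.env(parent = emptyenv())
cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    d <- simulate_case_control(model = "additive", theta = 2, maf = 0.3,
                               n_cases = 250, n_controls = 250,
                               n_background = 18, seed = 11)
    cfg <- sampler_config(iterations = 750, burn_in = 10, kept = 50,
                          seed = 12)
    .fit_cache$fit <- bnn(d, config = cfg)
    .fit_cache$data <- d
  }
  list(fit = .fit_cache$fit, data = .fit_cache$data)
}

# independent finite-difference gradient of a scalar function
fd_grad <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
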