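# Leapfrog integrator, HMC update, Gibbs variance updates and the chain.

test_that("leapfrog with zero steps (and tiny step size) is the identity", {
  grad <- function(q) -q
  q0 <- c(1, -2); p0 <- c(0.5, 0.3)
  out <- leapfrog(q0, p0, step_size = 0.1, n_steps = 0, grad_fn = grad)
  expect_identical(out$position, q0)
  expect_identical(out$momentum, p0)
  out2 <- leapfrog(q0, p0, step_size = 1e-10, n_steps = 1, grad_fn = grad)
  expect_equal(out2$position, q0, tolerance = 1e-8)
  expect_equal(out2$momentum, p0, tolerance = 1e-8)
})

test_that("leapfrog matches the discrete harmonic-oscillator recurrence", {
  # standard Gaussian target: U(q) = q^2/2, grad log target = -q.
  # One leapfrog step is the linear map (q, p) -> A (q, p); L steps are A^L.
  eps <- 0.15; L <- 12
  A <- matrix(c(1 - eps^2 / 2, -eps + eps^3 / 4, eps, 1 - eps^2 / 2), 2, 2)
  M <- diag(2)
  for (i in seq_len(L)) M <- A %*% M
  q0 <- 0.8; p0 <- -0.35
  expected <- M %*% c(q0, p0)
  out <- leapfrog(q0, p0, eps, L, function(q) -q)
  expect_equal(c(out$position, out$momentum), drop(expected),
               tolerance = 1e-10)
})

test_that("leapfrog is time-reversible", {
  set.seed(21)
  p <- 4; h <- 2; n <- 15
  x <- toy_genotypes(n, p, seed = 22)
  y <- sample(c(0, 1), n, replace = TRUE)
  ptr <- epibnn:::bnn_model_ptr(x, y, h)
  d <- p * h + h + 2 * h + 2
  pv <- rep(0.8, d)
  grad <- function(z) drop(epibnn:::bnn_grad_ptr(ptr, z, pv))
  q0 <- rnorm(d, 0, 0.3); p0 <- rnorm(d)
  fwd <- leapfrog(q0, p0, 0.05, 20, grad)
  back <- leapfrog(fwd$position, -fwd$momentum, 0.05, 20, grad)
  expect_equal(back$position, q0, tolerance = 1e-8)
  expect_equal(-back$momentum, p0, tolerance = 1e-8)
})

test_that("one leapfrog step preserves phase-space volume", {
  # 1-D double-well potential; Jacobian of (q,p) -> step(q,p) by finite
  # differences should have determinant 1
  grad <- function(q) -(q^3 - q)   # log target = -(q^4/4 - q^2/2)
  step <- function(z) {
    out <- leapfrog(z[1], z[2], step_size = 0.2, n_steps = 1, grad_fn = grad)
    c(out$position, out$momentum)
  }
  z0 <- c(0.7, -0.4)
  eps <- 1e-6
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + eps; zm[j] <- zm[j] - eps
    J[, j] <- (step(zp) - step(zm)) / (2 * eps)
  }
  expect_equal(det(J), 1, tolerance = 1e-8)
})

test_that("small step sizes give near-certain acceptance", {
  set.seed(23)
  grad <- function(q) -q
  lp <- function(q) -0.5 * sum(q^2)
  q <- rnorm(3); mom <- rnorm(3)
  acc <- replicate(200, {
    st <- hmc_update(q, mom, lp, grad, step_size = 0.01, n_steps = 5,
                     alpha = 0)
    q <<- st$position; mom <<- st$momentum
    st$accepted
  })
  expect_gt(mean(acc), 0.95)
})

test_that("HMC recovers the moments of a bivariate Gaussian", {
  set.seed(24)
  grad <- function(q) -q
  lp <- function(q) -0.5 * sum(q^2)
  q <- c(2, -2); mom <- rnorm(2)
  n_iter <- 20000
  draws <- matrix(NA_real_, n_iter, 2)
  for (i in seq_len(n_iter)) {
    st <- hmc_update(q, mom, lp, grad, step_size = 0.4, n_steps = 8,
                     alpha = 0.5)
    q <- st$position; mom <- st$momentum
    draws[i, ] <- q
  }
  expect_equal(colMeans(draws), c(0, 0), tolerance = 0.05)
  expect_equal(apply(draws, 2, var), c(1, 1), tolerance = 0.1)
})

test_that("non-finite gradients abort the trajectory and count as rejection", {
  grad <- function(q) rep(NaN, length(q))
  lp <- function(q) 0
  st <- hmc_update(c(1, 1), c(0, 0), lp, grad, step_size = 0.1, n_steps = 3,
                   alpha = 0)
  expect_false(st$accepted)
  expect_equal(st$position, c(1, 1))
})

test_that("Gibbs update draws from IG(alpha0 + m/2, beta0 + SS/2)", {
  # all group weights zero, alpha0 = 5, beta0 = 2, h = 5:
  # full conditional is IG(7.5, 2), mean 2/6.5
  set.seed(25)
  st <- zero_state(p = 3, h = 5)
  pr <- bnn_prior(ard_variances = rep(1, 3), output_variance = 1,
                  ard_hyper = c(5, 2))
  draws <- replicate(100000 %/% 3,
                     gibbs_update_variances(st, pr)$ard_variances)
  expect_equal(mean(draws), 2 / 6.5, tolerance = 0.01)
})

test_that("larger group sum-of-squares shifts the variance draws upward", {
  set.seed(26)
  h <- 5
  mk <- function(ss) {
    w <- matrix(0, h, 2); w[, 2] <- sqrt(ss / h)
    bnn_state(w, rep(0, h), matrix(0.1, 2, h), c(0, 0))
  }
  pr <- bnn_prior(ard_variances = c(1, 1), output_variance = 1)
  d_small <- replicate(4000, gibbs_update_variances(mk(0.5), pr)$ard_variances[2])
  d_large <- replicate(4000, gibbs_update_variances(mk(8), pr)$ard_variances[2])
  expect_gt(median(d_large), median(d_small))
})

test_that("Gibbs full conditional matches a numerically normalized density", {
  # one group of m weights: prior IG(a0, b0) x N(w; 0, s2) likelihood.
  # Build the exact CDF on a grid and KS-test the sampler's draws.
  set.seed(27)
  a0 <- 5; b0 <- 2; h <- 4
  w <- c(0.9, -0.4, 0.2, 1.1)
  st <- bnn_state(matrix(w, h, 1), rep(0, h), matrix(0, 2, h), c(0, 0))
  pr <- bnn_prior(ard_variances = 1, output_variance = 1,
                  ard_hyper = c(a0, b0))
  draws <- replicate(10000, gibbs_update_variances(st, pr)$ard_variances[1])
  logdens <- function(s2) (-a0 - 1) * log(s2) - b0 / s2 +
    sum(dnorm(w, 0, sqrt(s2), log = TRUE))
  grid <- seq(1e-4, 8, length.out = 20000)
  ld <- vapply(grid, logdens, numeric(1))
  dens <- exp(ld - max(ld))
  cdf <- cumsum(dens) / sum(dens)
  cdf_fun <- approxfun(grid, cdf, yleft = 0, yright = 1)
  ks <- suppressWarnings(ks.test(draws, cdf_fun))
  expect_gt(ks$p.value, 0.01)
})

test_that("chain records burn-in + kept draws at the implied thinning", {
  cfg <- sampler_config(iterations = 5000, burn_in = 25, kept = 100, seed = 1)
  expect_equal(cfg$thinning, 40)
  d <- simulate_case_control(model = "additive", theta = 1, maf = 0.3,
                             n_cases = 15, n_controls = 15, n_background = 1,
                             seed = 28)
  fit <- bnn(d, hidden = 2, config = cfg)
  expect_equal(nrow(fit$par_draws), 125)
  expect_equal(nrow(fit$ard_draws), 125)
  expect_equal(fit$config$thinning, 40)
  expect_gte(fit$acceptance_rate, 0)
  expect_lte(fit$acceptance_rate, 1)
})

test_that("fixed seeds reproduce the chain exactly", {
  d <- simulate_case_control(model = "additive", theta = 2, maf = 0.3,
                             n_cases = 40, n_controls = 40, n_background = 3,
                             seed = 29)
  cfg <- sampler_config(iterations = 120, burn_in = 4, kept = 20, seed = 30)
  f1 <- bnn(d, hidden = 3, config = cfg)
  f2 <- bnn(d, hidden = 3, config = cfg)
  expect_identical(f1$par_draws, f2$par_draws)
  expect_identical(f1$ard_draws, f2$ard_draws)
  expect_identical(f1$acceptance_rate, f2$acceptance_rate)
})

test_that("covariates join the model but not the ARD report", {
  d <- simulate_case_control(model = "additive", theta = 2, maf = 0.3,
                             n_cases = 60, n_controls = 60, n_background = 6,
                             seed = 35)
  covs <- cbind(cluster = rep(c(0, 1, 2), length.out = 120))
  cfg <- sampler_config(iterations = 150, burn_in = 3, kept = 20, seed = 36)
  fit <- bnn(d$genotypes, d$phenotype, covariates = covs, hidden = 3,
             config = cfg)
  expect_equal(fit$n_covariates, 1L)
  expect_equal(fit$shape$p, 9L)          # 8 SNPs + 1 covariate input
  expect_equal(ncol(fit$ard_draws), 8L)  # ARD groups are SNPs only
  expect_equal(length(fit$cov_draws), nrow(fit$par_draws))
  expect_true(all(fit$cov_draws > 0))
  rep <- ard_test(fit)
  expect_equal(nrow(rep), 8)             # covariate never reported
  pr <- predict(fit)
  expect_equal(length(pr), 120)
})

test_that("degenerate single-class phenotypes are rejected", {
  x <- toy_genotypes(10, 3)
  expect_error(bnn(x, rep(1, 10)), "degenerate")
})

test_that("acceptance rate stays in a healthy band on a moderate dataset", {
  res <- cached_small_fit()
  expect_gt(res$fit$acceptance_rate, 0.3)
  expect_lt(res$fit$acceptance_rate, 0.99)
})
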