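# Forward pass, likelihood, prior density and log-posterior gradient.

test_that("zero-weight network outputs probability 0.5 for every row", {
  st <- zero_state(p = 4, h = 3)
  x <- toy_genotypes(10, 4)
  expect_equal(bnn_forward(st, x), rep(0.5, 10))
})

test_that("two-class softmax probabilities are complementary", {
  for (seed in 1:5) {
    st <- rand_state(p = 6, h = 4, sd = 1.5, seed = seed)
    x <- toy_genotypes(25, 6, seed = seed + 100)
    f1 <- bnn_forward(st, x)
    expect_true(all(f1 > 0 & f1 < 1))
    # recompute f2 from the softmax directly and check f1 + f2 = 1
    z <- sweep(x %*% t(st$hidden_weights), 2, st$hidden_biases, "+")
    a <- sweep((1 / (1 + exp(-z))) %*% t(st$output_weights), 2,
               st$output_biases, "+")
    f2 <- exp(a[, 2]) / (exp(a[, 1]) + exp(a[, 2]))
    expect_equal(f1 + f2, rep(1, 25), tolerance = 1e-12)
  }
})

test_that("forward pass matches a step-by-step scalar evaluation", {
  # 1 input, 1 hidden unit, hand-chosen weights
  st <- bnn_state(hidden_weights = matrix(0.7, 1, 1), hidden_biases = -0.2,
                  output_weights = matrix(c(1.3, -0.4), 2, 1),
                  output_biases = c(0.1, 0.5))
  x <- matrix(2)
  hk <- 1 / (1 + exp(-(-0.2 + 0.7 * 2)))      # hidden activation
  a1 <- 0.1 + 1.3 * hk                        # output pre-activations
  a2 <- 0.5 - 0.4 * hk
  expected <- exp(a1) / (exp(a1) + exp(a2))   # softmax, class 1
  expect_equal(bnn_forward(st, x), expected, tolerance = 1e-14)
})

test_that("forward pass validates dimensions and finiteness", {
  st <- rand_state(p = 3, h = 2, seed = 1)
  expect_error(bnn_forward(st, matrix(0, 5, 4)), "columns")
  expect_error(bnn_forward(st, matrix(c(1, NA, 0), 1, 3)), "finite")
  expect_error(bnn_state(matrix(Inf, 2, 3), rep(0, 2), matrix(0, 2, 2),
                         c(0, 0)), "finite")
})

test_that("log-likelihood of the symmetric network is n log(1/2)", {
  st <- zero_state(p = 5, h = 5)
  x <- toy_genotypes(10, 5)
  y <- rep(c(1, 0), 5)
  expect_equal(bnn_log_likelihood(st, x, y), 10 * log(0.5))
})

test_that("log-likelihood agrees with an observation-by-observation sum", {
  st <- rand_state(p = 4, h = 3, sd = 1, seed = 3)
  x <- toy_genotypes(5, 4, seed = 4)
  y <- c(1, 0, 0, 1, 1)
  f1 <- bnn_forward(st, x)
  byhand <- 0
  for (i in 1:5)
    byhand <- byhand + y[i] * log(f1[i]) + (1 - y[i]) * log(1 - f1[i])
  ll <- bnn_log_likelihood(st, x, y)
  expect_equal(ll, byhand, tolerance = 1e-12)
  expect_lte(ll, 0)
})

test_that("log-likelihood approaches 0 from below under perfect prediction", {
  # scale up a separating state: one informative input drives the output
  x <- matrix(c(2, 2, 0, 0), 4, 1)
  y <- c(1, 1, 0, 0)
  lls <- vapply(c(1, 5, 25), function(s) {
    st <- bnn_state(matrix(s, 1, 1), -s, matrix(c(s, -s), 2, 1), c(0, s))
    bnn_log_likelihood(st, x, y)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))  # increasing toward 0
  expect_true(all(lls < 0))
  expect_gt(lls[3], -1e-6)
})

test_that("extreme states do not produce -Inf likelihood (clamping)", {
  x <- matrix(c(2, 0), 2, 1)
  y <- c(0, 1)  # mislabelled on purpose to force log of a tiny probability
  st <- bnn_state(matrix(500, 1, 1), -250, matrix(c(1000, -1000), 2, 1),
                  c(-500, 500))
  ll <- bnn_log_likelihood(st, x, y)
  expect_true(is.finite(ll))
  expect_equal(ll, 2 * log(1e-12), tolerance = 1e-6)
})

test_that("log-prior equals an independent product of normal densities", {
  set.seed(5)
  st <- rand_state(p = 4, h = 3, sd = 0.8)
  pr <- rand_prior(4)
  # oracle: accumulate dnorm terms parameter by parameter
  oracle <- 0
  for (j in 1:4) for (k in 1:3)
    oracle <- oracle + dnorm(st$hidden_weights[k, j], 0,
                             sqrt(pr$ard_variances[j]), log = TRUE)
  for (k in 1:3)
    oracle <- oracle + dnorm(st$hidden_biases[k], 0, 10, log = TRUE)
  for (cc in 1:2) for (k in 1:3)
    oracle <- oracle + dnorm(st$output_weights[cc, k], 0,
                             sqrt(pr$output_variance), log = TRUE)
  for (cc in 1:2)
    oracle <- oracle + dnorm(st$output_biases[cc], 0, 10, log = TRUE)
  expect_equal(bnn_log_prior(st, pr), oracle, tolerance = 1e-12)
})

test_that("zero-weight log-prior is the sum of normalizers and doubling a weight lowers it", {
  pr <- bnn_prior(ard_variances = rep(0.5, 3), output_variance = 1)
  st0 <- zero_state(p = 3, h = 2)
  normalizers <- 2 * 3 * dnorm(0, 0, sqrt(0.5), log = TRUE) +
    2 * dnorm(0, 0, 10, log = TRUE) +
    4 * dnorm(0, 0, 1, log = TRUE) +
    2 * dnorm(0, 0, 10, log = TRUE)
  expect_equal(bnn_log_prior(st0, pr), normalizers)
  st1 <- st0; st1$hidden_weights[1, 1] <- 0.4
  st2 <- st0; st2$hidden_weights[1, 1] <- 0.8
  expect_lt(bnn_log_prior(st1, pr), bnn_log_prior(st0, pr))
  expect_lt(bnn_log_prior(st2, pr), bnn_log_prior(st1, pr))
})

test_that("non-positive variances are rejected", {
  expect_error(bnn_prior(ard_variances = c(1, 0), output_variance = 1))
  expect_error(bnn_prior(ard_variances = 1, output_variance = -2))
})

test_that("gradient matches central finite differences on every block", {
  set.seed(7)
  p <- 5; h <- 3; n <- 20
  x <- toy_genotypes(n, p, seed = 8)
  y <- sample(c(0, 1), n, replace = TRUE)
  st <- rand_state(p, h, sd = 0.6)
  pr <- rand_prior(p)
  g <- bnn_grad_log_posterior(st, pr, x, y)
  gflat <- c(as.numeric(t(g$hidden_weights)), g$hidden_biases,
             as.numeric(t(g$output_weights)), g$output_biases)
  par0 <- c(as.numeric(t(st$hidden_weights)), st$hidden_biases,
            as.numeric(t(st$output_weights)), st$output_biases)
  f <- function(par) {
    s <- epibnn:::unpack_state(par, p, h)
    bnn_log_likelihood(s, x, y) + bnn_log_prior(s, pr)
  }
  fd <- fd_grad(f, par0)
  expect_equal(gflat, fd, tolerance = 1e-4)
})

test_that("gradient is near zero at a local posterior maximum", {
  set.seed(9)
  p <- 2; h <- 2; n <- 40
  x <- toy_genotypes(n, p, seed = 10)
  y <- as.numeric(runif(n) < 0.3 + 0.2 * (x[, 1] == 2))
  pr <- bnn_prior(ard_variances = rep(1, p), output_variance = 1)
  par <- rnorm(p * h + h + 2 * h + 2, 0, 0.1)
  ptr <- epibnn:::bnn_model_ptr(x, y, h)
  pv <- epibnn:::expand_prior_var(pr, p, 0, h)
  opt <- optim(par, fn = function(z) -sum(epibnn:::bnn_logpost_ptr(ptr, z, pv)),
               gr = function(z) -drop(epibnn:::bnn_grad_ptr(ptr, z, pv)),
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
  gnorm <- sqrt(sum(epibnn:::bnn_grad_ptr(ptr, opt$par, pv)^2))
  expect_lt(gnorm, 1e-3)
})

test_that("duplicated SNP columns receive identical gradient blocks", {
  set.seed(11)
  p <- 4; h <- 3; n <- 30
  x <- toy_genotypes(n, p, seed = 12)
  x[, 2] <- x[, 1]  # duplicate
  y <- sample(c(0, 1), n, replace = TRUE)
  st <- rand_state(p, h, sd = 0.5)
  st$hidden_weights[, 2] <- st$hidden_weights[, 1]  # identical init
  pr <- bnn_prior(ard_variances = rep(0.7, p), output_variance = 1)
  g <- bnn_grad_log_posterior(st, pr, x, y)
  expect_equal(g$hidden_weights[, 1], g$hidden_weights[, 2])
})

test_that("likelihood is invariant to relabelling hidden units", {
  set.seed(13)
  st <- rand_state(p = 4, h = 4, sd = 1)
  x <- toy_genotypes(15, 4, seed = 14)
  y <- sample(c(0, 1), 15, replace = TRUE)
  perm <- c(3, 1, 4, 2)
  stp <- bnn_state(st$hidden_weights[perm, ], st$hidden_biases[perm],
                   st$output_weights[, perm], st$output_biases)
  expect_equal(bnn_log_likelihood(st, x, y),
               bnn_log_likelihood(stp, x, y), tolerance = 1e-12)
})

test_that("compiled and pure-R log posteriors agree", {
  set.seed(15)
  p <- 6; h <- 3; n <- 25
  x <- toy_genotypes(n, p, seed = 16)
  y <- sample(c(0, 1), n, replace = TRUE)
  st <- rand_state(p, h, sd = 0.7)
  pr <- rand_prior(p)
  ptr <- epibnn:::bnn_model_ptr(x, y, h)
  pv <- epibnn:::expand_prior_var(pr, p, 0, h)
  cpp <- epibnn:::bnn_logpost_ptr(ptr, epibnn:::pack_state(st), pv)
  expect_equal(cpp[1], bnn_log_likelihood(st, x, y), tolerance = 1e-10)
  expect_equal(cpp[2], bnn_log_prior(st, pr), tolerance = 1e-10)
  expect_equal(drop(epibnn:::bnn_forward_ptr(ptr, epibnn:::pack_state(st))),
               bnn_forward(st, x), tolerance = 1e-12)
})
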