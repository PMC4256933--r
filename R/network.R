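# The network model: one hidden layer of logistic units feeding a two-unit
# softmax output. States and priors are plain validated lists; heavy lifting
# (forward pass, gradients) is done in compiled code during sampling, with
# pure-R reference implementations here used by the lightweight operations
# and exercised against the compiled route in the tests.

#' Network architecture descriptor
#'
#' @param p number of input variables (SNPs plus covariates).
#' @param h number of hidden units.
#' @return An object of class `bnn_shape`.
#' @export
bnn_shape <- function(p, h) {
  stopifnot(p >= 1, h >= 1)
  structure(list(p = as.integer(p), h = as.integer(h), c = 2L),
            class = "bnn_shape")
}

#' Network weight/bias state
#'
#' Container for all weights and biases of the one-hidden-layer softmax
#' network: `hidden_weights[k, j]` connects input `j` to hidden unit `k`;
#' `output_weights[c, k]` connects hidden unit `k` to output unit `c`.
#'
#' @param hidden_weights h x p matrix.
#' @param hidden_biases length-h vector.
#' @param output_weights 2 x h matrix.
#' @param output_biases length-2 vector.
#' @return An object of class `bnn_state`.
#' @export
bnn_state <- function(hidden_weights, hidden_biases, output_weights,
                      output_biases) {
  hidden_weights <- as.matrix(hidden_weights)
  output_weights <- as.matrix(output_weights)
  h <- nrow(hidden_weights)
  p <- ncol(hidden_weights)
  stopifnot(length(hidden_biases) == h,
            nrow(output_weights) == 2L, ncol(output_weights) == h,
            length(output_biases) == 2L)
  if (!all(is.finite(hidden_weights)) || !all(is.finite(hidden_biases)) ||
      !all(is.finite(output_weights)) || !all(is.finite(output_biases)))
    stop("network state contains non-finite values")
  structure(list(hidden_weights = hidden_weights,
                 hidden_biases = as.numeric(hidden_biases),
                 output_weights = output_weights,
                 output_biases = as.numeric(output_biases),
                 shape = bnn_shape(p, h)),
            class = "bnn_state")
}

#' ARD prior state
#'
#' Per-input-group variances and their Inverse-Gamma hyperparameters. Each
#' SNP's hidden-layer weight group has its own variance `ard_variances[j]`;
#' covariate hidden-layer weights (if any) share one variance; all output
#' weights share `output_variance`; biases have a fixed Gaussian variance and
#' belong to no ARD group.
#'
#' @param ard_variances positive vector, one entry per SNP group.
#' @param output_variance positive scalar for the output-weight group.
#' @param ard_hyper `c(alpha0, beta0)` of the Inverse-Gamma on the ARD
#'   variances (default `c(5, 2)`).
#' @param output_hyper `c(alpha0, beta0)` of the Inverse-Gamma on the shared
#'   output-weight variance (default `c(0.1, 0.1)`).
#' @param bias_variance fixed prior variance of all biases (default 100).
#' @param covariate_variance shared variance of the covariate group, or `NULL`
#'   when the model has no covariates.
#' @return An object of class `bnn_prior`.
#' @export
bnn_prior <- function(ard_variances, output_variance,
                      ard_hyper = c(5, 2), output_hyper = c(0.1, 0.1),
                      bias_variance = 100, covariate_variance = NULL) {
  stopifnot(all(ard_variances > 0), output_variance > 0,
            all(ard_hyper > 0), all(output_hyper > 0), bias_variance > 0)
  if (!is.null(covariate_variance)) stopifnot(covariate_variance > 0)
  structure(list(ard_variances = as.numeric(ard_variances),
                 output_variance = as.numeric(output_variance),
                 ard_hyper = as.numeric(ard_hyper),
                 output_hyper = as.numeric(output_hyper),
                 bias_variance = as.numeric(bias_variance),
                 covariate_variance = covariate_variance),
            class = "bnn_prior")
}

# ---- parameter packing -------------------------------------------------
# Flat layout used by the sampler and compiled code (column-major):
#   [ vec(t(hidden_weights)) : p*h ][ hidden_biases : h ]
#   [ vec(t(output_weights)) : h*2 ][ output_biases : 2 ]

pack_state <- function(state) {
  c(as.numeric(t(state$hidden_weights)), state$hidden_biases,
    as.numeric(t(state$output_weights)), state$output_biases)
}

unpack_state <- function(par, p, h) {
  ph <- p * h
  bnn_state(hidden_weights = t(matrix(par[seq_len(ph)], p, h)),
            hidden_biases = par[ph + seq_len(h)],
            output_weights = t(matrix(par[ph + h + seq_len(2 * h)], h, 2)),
            output_biases = par[ph + 3 * h + 1:2])
}

# Expand group variances into a per-parameter prior-variance vector matching
# the flat layout. `p_snp` SNP columns come first, then `q` covariate columns.
expand_prior_var <- function(prior, p_snp, q, h) {
  v_in <- prior$ard_variances
  if (q > 0) v_in <- c(v_in, rep(prior$covariate_variance, q))
  c(rep(v_in, h),                       # hidden weights, column-major p x h
    rep(prior$bias_variance, h),        # hidden biases
    rep(prior$output_variance, 2 * h),  # output weights
    rep(prior$bias_variance, 2))        # output biases
}

.as_input_matrix <- function(inputs, p) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != p)
    stop(sprintf("input matrix has %d columns but the network expects %d",
                 ncol(inputs), p))
  if (!all(is.finite(inputs))) stop("inputs contain non-finite values")
  storage.mode(inputs) <- "double"
  inputs
}

#' Forward pass of the network
#'
#' Computes the class-1 (case) probability for every row of `inputs`: each
#' hidden unit applies a logistic transformation to a linear combination of
#' the inputs, and the output layer applies the two-class softmax to a linear
#' combination of the hidden activations, so the two class probabilities sum
#' to one exactly.
#'
#' @param state a [bnn_state()].
#' @param inputs numeric matrix, one row per observation, `p` columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
bnn_forward <- function(state, inputs) {
  stopifnot(inherits(state, "bnn_state"))
  x <- .as_input_matrix(inputs, state$shape$p)
  z <- sweep(x %*% t(state$hidden_weights), 2, state$hidden_biases, "+")
  hact <- plogis_mat(z)
  act <- sweep(hact %*% t(state$output_weights), 2, state$output_biases, "+")
  # softmax over 2 classes, computed stably via the difference
  f1 <- 1 / (1 + exp(-(act[, 1] - act[, 2])))
  if (!all(is.finite(f1))) stop("non-finite values in forward pass")
  f1
}

plogis_mat <- function(z) 1 / (1 + exp(-z))

.clamp_prob <- function(p, floor = 1e-12) pmin(pmax(p, floor), 1 - floor)

#' Binomial log-likelihood of a network state
#'
#' Sum over observations of `y_i1 log f1(x_i) + y_i2 log(1 - f1(x_i))`, with
#' the class probability clamped to `[1e-12, 1 - 1e-12]` before taking logs so
#' extreme states cannot produce `-Inf`.
#'
#' @param state a [bnn_state()].
#' @param x input matrix (rows = observations).
#' @param y binary phenotype vector (1 = case).
#' @return Scalar log-likelihood (always <= 0).
#' @export
bnn_log_likelihood <- function(state, x, y) {
  f1 <- .clamp_prob(bnn_forward(state, x))
  y <- as.numeric(y)
  stopifnot(length(y) == length(f1), all(y %in% c(0, 1)))
  sum(y * log(f1) + (1 - y) * log(1 - f1))
}

#' Log prior density of a network state
#'
#' Independent zero-mean Gaussians: each SNP group's hidden weights share that
#' group's ARD variance, covariate hidden weights share one variance, output
#' weights share the output variance, and biases have the fixed bias variance.
#' Normalising constants are included, so this is the full log density for the
#' given variances.
#'
#' @param state a [bnn_state()].
#' @param prior a [bnn_prior()].
#' @param n_covariates number of trailing input columns that are covariates
#'   rather than SNPs (default 0).
#' @return Scalar log density.
#' @export
bnn_log_prior <- function(state, prior, n_covariates = 0) {
  stopifnot(inherits(state, "bnn_state"), inherits(prior, "bnn_prior"))
  p <- state$shape$p
  q <- as.integer(n_covariates)
  p_snp <- p - q
  stopifnot(length(prior$ard_variances) == p_snp,
            q == 0 || !is.null(prior$covariate_variance))
  par <- pack_state(state)
  v <- expand_prior_var(prior, p_snp, q, state$shape$h)
  sum(dnorm(par, 0, sqrt(v), log = TRUE))
}

#' Gradient of the log posterior with respect to weights and biases
#'
#' Gradient of `bnn_log_likelihood + bnn_log_prior` with the prior variances
#' held fixed, computed by backpropagation in compiled code.
#'
#' @inheritParams bnn_log_prior
#' @param x input matrix.
#' @param y binary phenotype vector.
#' @return A list with the same structure (and dimensions) as the state:
#'   `hidden_weights`, `hidden_biases`, `output_weights`, `output_biases`.
#' @export
bnn_grad_log_posterior <- function(state, prior, x, y, n_covariates = 0) {
  stopifnot(inherits(state, "bnn_state"), inherits(prior, "bnn_prior"))
  p <- state$shape$p
  h <- state$shape$h
  q <- as.integer(n_covariates)
  x <- .as_input_matrix(x, p)
  ptr <- bnn_model_ptr(x, as.numeric(y), h)
  v <- expand_prior_var(prior, p - q, q, h)
  g <- bnn_grad_ptr(ptr, pack_state(state), v)
  gs <- unpack_state(g, p, h)
  list(hidden_weights = gs$hidden_weights, hidden_biases = gs$hidden_biases,
       output_weights = gs$output_weights, output_biases = gs$output_biases)
}
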