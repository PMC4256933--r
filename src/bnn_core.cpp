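// Core numerics for the Bayesian neural network: forward pass, log posterior
// and its gradient. The design matrix is held in an external pointer so the
// sampler can evaluate ~10^5 gradients per chain without copying data.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double PROB_FLOOR = 1e-12;

struct BnnModel {
  arma::mat X;   // n x P inputs (SNP minor-allele counts, then covariates)
  arma::vec y1;  // 1 = case, 0 = control
  arma::uword n, P, h;
  // preallocated workspace
  arma::mat Z, H, dZ;
  arma::vec delta, f1, r, wdiff;
  BnnModel(const arma::mat& X_, const arma::vec& y_, int h_)
      : X(X_), y1(y_), n(X_.n_rows), P(X_.n_cols), h((arma::uword)h_),
        Z(n, h), H(n, h), dZ(n, h), delta(n), f1(n), r(n), wdiff(h) {}
};

// Parameter layout (column-major throughout):
//   [ vec(wh) : P*h ][ bh : h ][ vec(wo) : h*2 ][ B : 2 ]
// wh is P x h (input j, hidden unit k); wo is h x 2.
inline arma::uword npar(const BnnModel& M) { return M.P * M.h + M.h + 2 * M.h + 2; }

// Forward pass; fills Z, H, delta = A1 - A2, f1 = logistic(delta).
void forward(BnnModel& M, const arma::vec& par) {
  const arma::uword Ph = M.P * M.h;
  const arma::mat wh(const_cast<double*>(par.memptr()), M.P, M.h, false, true);
  const arma::rowvec bh(const_cast<double*>(par.memptr()) + Ph, M.h, false, true);
  const double* wo = par.memptr() + Ph + M.h;
  const double* B = wo + 2 * M.h;
  M.Z = M.X * wh;
  M.Z.each_row() += bh;
  M.H = 1.0 / (1.0 + arma::exp(-M.Z));
  for (arma::uword k = 0; k < M.h; ++k) M.wdiff[k] = wo[k] - wo[M.h + k];
  M.delta = M.H * M.wdiff;
  M.delta += B[0] - B[1];
  M.f1 = 1.0 / (1.0 + arma::exp(-M.delta));
}

double log_lik(const BnnModel& M) {
  double ll = 0.0;
  for (arma::uword i = 0; i < M.n; ++i) {
    double p = M.f1[i];
    if (p < PROB_FLOOR) p = PROB_FLOOR;
    if (p > 1.0 - PROB_FLOOR) p = 1.0 - PROB_FLOOR;
    ll += M.y1[i] * std::log(p) + (1.0 - M.y1[i]) * std::log(1.0 - p);
  }
  return ll;
}

double log_prior(const arma::vec& par, const arma::vec& prior_var) {
  double lp = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (arma::uword i = 0; i < par.n_elem; ++i)
    lp += -0.5 * par[i] * par[i] / prior_var[i] - 0.5 * (l2pi + std::log(prior_var[i]));
  return lp;
}

}  // namespace

// [[Rcpp::export]]
SEXP bnn_model_ptr(const arma::mat& X, const arma::vec& y1, int h) {
  XPtr<BnnModel> p(new BnnModel(X, y1, h), true);
  return p;
}

// [[Rcpp::export]]
arma::vec bnn_forward_ptr(SEXP ptr, const arma::vec& par) {
  XPtr<BnnModel> M(ptr);
  if (par.n_elem != npar(*M)) stop("parameter vector has wrong length");
  forward(*M, par);
  return M->f1;
}

// Returns c(log_likelihood, log_prior).
// [[Rcpp::export]]
arma::vec bnn_logpost_ptr(SEXP ptr, const arma::vec& par, const arma::vec& prior_var) {
  XPtr<BnnModel> M(ptr);
  if (par.n_elem != npar(*M)) stop("parameter vector has wrong length");
  forward(*M, par);
  arma::vec out(2);
  out[0] = log_lik(*M);
  out[1] = log_prior(par, prior_var);
  return out;
}

// Gradient of log_likelihood + log_prior w.r.t. all weights and biases
// (prior variances held fixed).
// [[Rcpp::export]]
arma::vec bnn_grad_ptr(SEXP ptr, const arma::vec& par, const arma::vec& prior_var) {
  XPtr<BnnModel> Mp(ptr);
  BnnModel& M = *Mp;
  if (par.n_elem != npar(M)) stop("parameter vector has wrong length");
  forward(M, par);
  const arma::uword Ph = M.P * M.h;
  arma::vec g(par.n_elem);

  M.r = M.y1 - M.f1;                       // d loglik / d delta
  // output layer: A1 = B1 + H wo1, A2 = B2 + H wo2; dA1 = r, dA2 = -r
  arma::vec dwo1 = M.H.t() * M.r;          // h
  double rsum = arma::accu(M.r);
  // hidden layer
  M.dZ = (M.r * M.wdiff.t()) % M.H % (1.0 - M.H);  // n x h
  arma::mat dwh(g.memptr(), M.P, M.h, false, true);
  dwh = M.X.t() * M.dZ;                    // P x h, written into g
  double* gp = g.memptr();
  arma::rowvec dbh = arma::sum(M.dZ, 0);
  for (arma::uword k = 0; k < M.h; ++k) gp[Ph + k] = dbh[k];
  for (arma::uword k = 0; k < M.h; ++k) {
    gp[Ph + M.h + k] = dwo1[k];
    gp[Ph + M.h + M.h + k] = -dwo1[k];
  }
  gp[Ph + 3 * M.h] = rsum;
  gp[Ph + 3 * M.h + 1] = -rsum;
  // prior gradient
  g -= par / prior_var;
  return g;
}
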