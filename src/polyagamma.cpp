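// Polya-Gamma augmentation core.
//
// rpg() draws PG(1, z) variates exactly by Devroye's alternating-series
// method (rejection from a tilted Jacobi density truncated at t = 0.64).
// gibbs_logistic_chain() runs one chain of the exact conjugate Gibbs
// sampler for logistic regression with independent normal priors:
//   omega_i | beta ~ PG(1, x_i' beta),  beta | omega ~ N(m, V),
//   V = (X' Omega X + B^-1)^-1,  m = V (X' kappa + B^-1 b0),  kappa = y - 1/2.
// All randomness goes through R's RNG so set.seed() governs everything.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// n-th coefficient of the alternating series for the Jacobi density at x
static double a_coef(int n, double x) {
  double nph = n + 0.5;
  if (x > TRUNC)
    return M_PI * nph * std::exp(-nph * nph * M_PI * M_PI * x / 2.0);
  return M_PI * nph * std::pow(2.0 / (M_PI * x), 1.5) *
         std::exp(-2.0 * nph * nph / x);
}

// probability of proposing from the exponential tail (x > TRUNC)
static double mass_texpon(double Z) {
  double t = TRUNC;
  double fz = M_PI * M_PI / 8.0 + Z * Z / 2.0;
  double b = std::sqrt(1.0 / t) * (t * Z - 1.0);
  double a = -std::sqrt(1.0 / t) * (t * Z + 1.0);
  double x0 = std::log(fz) + fz * t;
  double xb = x0 - Z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + Z + R::pnorm(a, 0.0, 1.0, 1, 1);
  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// inverse-Gaussian(mu = 1/Z, lambda = 1) truncated to (0, TRUNC)
static double rtigauss(double Z) {
  double t = TRUNC;
  double X = t + 1.0;
  if (Z < 1.0 / t) {  // mu > t: rejection with a truncated-chi proposal
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double E1, E2;
      do {
        E1 = R::exp_rand();
        E2 = R::exp_rand();
      } while (E1 * E1 > 2.0 * E2 / t);
      X = t / ((1.0 + t * E1) * (1.0 + t * E1));
      alpha = std::exp(-0.5 * Z * Z * X);
    }
  } else {
    double mu = 1.0 / Z;
    while (X > t) {
      double Y = R::norm_rand();
      Y = Y * Y;
      double muY = mu * Y;
      X = mu + 0.5 * mu * muY - 0.5 * mu * std::sqrt(4.0 * muY + muY * muY);
      if (R::unif_rand() > mu / (mu + X)) X = mu * mu / X;
    }
  }
  return X;
}

// single draw from PG(1, z); PG(1, z) = J*(1, z/2) / 4
static double rpg_one(double z) {
  double Z = std::fabs(z) * 0.5;
  double fz = M_PI * M_PI / 8.0 + Z * Z / 2.0;
  for (;;) {
    double X;
    if (R::unif_rand() < mass_texpon(Z))
      X = TRUNC + R::exp_rand() / fz;
    else
      X = rtigauss(Z);
    double S = a_coef(0, X);
    double Y = R::unif_rand() * S;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        S -= a_coef(n, X);
        if (Y <= S) return 0.25 * X;
      } else {
        S += a_coef(n, X);
        if (Y > S) break;
      }
    }
  }
}

//' @keywords internal
// [[Rcpp::export(name = ".rpg")]]
NumericVector rpg(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg_one(z[i]);
  return out;
}

// one chain of the PG Gibbs sampler for Bayesian logistic regression;
// returns the n_keep x p matrix of post-warmup coefficient draws
// [[Rcpp::export(name = ".gibbs_logistic_chain")]]
arma::mat gibbs_logistic_chain(const arma::mat& X, const arma::vec& y,
                               const arma::vec& prior_mean,
                               const arma::vec& prior_prec,
                               int n_keep, int warmup,
                               const arma::vec& beta_init) {
  int n = X.n_rows, p = X.n_cols;
  arma::vec beta = beta_init;
  arma::vec kappa = y - 0.5;
  arma::vec Xk = X.t() * kappa;
  arma::vec pb = prior_prec % prior_mean;
  arma::mat out(n_keep, p);
  for (int it = 0; it < warmup + n_keep; ++it) {
    arma::vec psi = X * beta;
    arma::vec omega(n);
    for (int i = 0; i < n; ++i) omega(i) = rpg_one(psi(i));
    arma::mat M = X.t() * (X.each_col() % omega);
    M.diag() += prior_prec;
    arma::mat L = arma::chol(M, "lower");
    arma::vec mu = arma::solve(arma::trimatl(L), Xk + pb);
    mu = arma::solve(arma::trimatu(L.t()), mu);
    arma::vec zdraw(p);
    for (int j = 0; j < p; ++j) zdraw(j) = R::norm_rand();
    beta = mu + arma::solve(arma::trimatu(L.t()), zdraw);
    if (it >= warmup) out.row(it - warmup) = beta.t();
  }
  return out;
}

// mean over rows of the quadrature sum: mean_i sum_k w_k logit^-1(c_i + d_k)
// [[Rcpp::export(name = ".logistic_mix_mean")]]
double logistic_mix_mean(const arma::vec& c, const arma::vec& d,
                         const arma::vec& w) {
  int n = c.n_elem, K = d.n_elem;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < K; ++k)
      s += w[k] / (1.0 + std::exp(-(c[i] + d[k])));
    acc += s;
  }
  return acc / n;
}
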