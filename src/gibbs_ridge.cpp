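// Gibbs sampler for Bayesian linear regression with a ridge prior.
//
// Model: y = alpha + X beta + eps, eps ~ N(0, sigma2 I)
//        beta | sigma2, tau2 ~ N(0, sigma2 tau2 I)
//        p(alpha) ~ const, p(sigma2) ~ 1/sigma2 (Jeffreys)
//        tau ~ half-Cauchy(0, 1), via the inverse-gamma scale mixture
//        tau2 | xi ~ IG(1/2, 1/xi), xi ~ IG(1/2, 1).
//
// Update order per sweep: beta, sigma2, tau2, xi. Uses R's RNG, so chains
// are reproducible through set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ IG(shape, rate); R::rgamma takes scale
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List gibbs_ridge_cpp(const arma::vec& y, const arma::mat& X,
                     int n_burnin, int n_samples,
                     int thinning_pool, int thin_by,
                     double tau2_fixed) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const arma::mat XtX = X.t() * X;
  const arma::vec Xty_base = X.t() * y;
  const arma::vec ones = arma::ones<arma::vec>(n);
  const arma::vec Xt1 = X.t() * ones;
  const double ybar = arma::mean(y);

  const bool estimate_tau2 = tau2_fixed <= 0.0;
  double tau2 = estimate_tau2 ? 1.0 : tau2_fixed;
  double xi = 1.0;
  double sigma2 = arma::var(y);
  if (!(sigma2 > 0.0)) sigma2 = 1.0;
  double alpha = ybar;
  arma::vec beta = arma::zeros<arma::vec>(p);

  const int n_thinned = (thin_by > 0 && thinning_pool > 0)
    ? thinning_pool / thin_by : 0;
  const int n_keep = n_samples + n_thinned;
  const int total = n_burnin + n_samples + thinning_pool;

  arma::mat beta_draws(n_keep, p);
  arma::vec alpha_draws(n_keep), sigma2_draws(n_keep), tau2_draws(n_keep);

  int kept = 0;
  for (int it = 0; it < total; ++it) {
    // beta | rest
    arma::mat A = XtX;
    A.diag() += 1.0 / tau2;
    arma::mat U = arma::chol(A); // A = U'U
    arma::vec rhs = Xty_base - alpha * Xt1;
    arma::vec m = arma::solve(A, rhs, arma::solve_opts::likely_sympd);
    arma::vec z(p);
    for (int j = 0; j < p; ++j) z(j) = R::norm_rand();
    beta = m + std::sqrt(sigma2) * arma::solve(arma::trimatu(U), z);

    // alpha | rest
    double resid_mean = ybar - arma::dot(Xt1, beta) / n;
    alpha = resid_mean + std::sqrt(sigma2 / n) * R::norm_rand();

    // sigma2 | rest
    arma::vec resid = y - alpha * ones - X * beta;
    double rss = arma::dot(resid, resid);
    double b2 = arma::dot(beta, beta);
    sigma2 = rinvgamma(0.5 * (n + p), 0.5 * (rss + b2 / tau2));

    // tau2, xi | rest
    if (estimate_tau2) {
      tau2 = rinvgamma(0.5 * (p + 1), 0.5 * b2 / sigma2 + 1.0 / xi);
      xi = rinvgamma(1.0, 1.0 + 1.0 / tau2);
    }

    if (!beta.is_finite() || !std::isfinite(sigma2) || !std::isfinite(tau2)) {
      stop("Divergent chain: non-finite draw at iteration %d", it + 1);
    }

    bool keep = false;
    if (it >= n_burnin && it < n_burnin + n_samples) {
      keep = true;
    } else if (it >= n_burnin + n_samples) {
      int k = it - (n_burnin + n_samples);
      keep = (thin_by > 0) && ((k + 1) % thin_by == 0) && (kept < n_keep);
    }
    if (keep) {
      beta_draws.row(kept) = beta.t();
      alpha_draws(kept) = alpha;
      sigma2_draws(kept) = sigma2;
      tau2_draws(kept) = tau2;
      ++kept;
    }
  }

  return List::create(
    _["beta"] = beta_draws.rows(0, kept - 1),
    _["alpha"] = alpha_draws.head(kept),
    _["sigma2"] = sigma2_draws.head(kept),
    _["tau2"] = tau2_draws.head(kept)
  );
}
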