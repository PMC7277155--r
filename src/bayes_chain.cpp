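#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Scaled-inverse-chi-square draw with nu degrees of freedom and scale S.
static inline double rscinvchisq(double nu, double S) {
  return nu * S / R::rchisq(nu);
}

// Single-site Gibbs sampler for the marker-effect mixture model
//   y_i = mu + sum_j Z_ij u_j delta_j + e_i,  e_i ~ N(0, sigma2_e / w_i)
// with P(delta_j = 0) = pi. BayesC: one common effect variance sigma2_u;
// BayesB: locus-specific variances with a scaled-inverse-chi-square prior
// (marginally a t prior on effects). delta_j and u_j are sampled jointly,
// integrating u_j out of the delta_j update. Weights w_i multiply each
// record's residual precision. Uses R's RNG: deterministic under set.seed().
//
// [[Rcpp::export]]
List cpp_bayes_chain(const arma::mat& Z, const arma::vec& y,
                     const arma::vec& w, const bool bayesB, const double pi,
                     const int chain_length, const int burn_in, const int thin,
                     const double nu_u, const double S_u,
                     const double nu_e, const double S_e,
                     const bool fix_var,
                     const double sigma2_u_init, const double sigma2_e_init) {
  const int n = Z.n_rows, m = Z.n_cols;
  const arma::vec& wv = w;
  const double sw = arma::accu(wv);

  // c_j = Z_j' W Z_j is constant across iterations (weights are fixed data)
  arma::vec zwz(m);
  for (int j = 0; j < m; ++j) {
    const double* zj = Z.colptr(j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += wv[i] * zj[i] * zj[i];
    zwz[j] = s;
  }

  arma::vec u(m, arma::fill::zeros);
  arma::vec sigma2_j(m);
  sigma2_j.fill(sigma2_u_init);
  double sigma2_u = sigma2_u_init;
  double sigma2_e = sigma2_e_init;
  double mu = arma::dot(wv, y) / sw;
  arma::vec e = y - mu;

  const int n_keep = (chain_length - burn_in) / thin;
  arma::mat U(n_keep, m, arma::fill::zeros);
  arma::vec keep_sigma2_u(n_keep), keep_sigma2_e(n_keep), keep_mu(n_keep);
  arma::vec u_sum(m, arma::fill::zeros);
  arma::vec incl(m, arma::fill::zeros);
  double mu_sum = 0.0, sig_u_sum = 0.0, sig_e_sum = 0.0;
  int n_post = 0, kept = 0;

  const bool always_in = (pi <= 0.0);
  const double log_prior_odds = always_in ? 0.0
    : std::log(1.0 - pi) - std::log(pi);

  for (int it = 1; it <= chain_length; ++it) {
    // intercept
    double ew = 0.0;
    for (int i = 0; i < n; ++i) ew += wv[i] * e[i];
    const double mu_new = (mu + ew / sw) + R::norm_rand() * std::sqrt(sigma2_e / sw);
    const double dmu = mu_new - mu;
    if (dmu != 0.0) { e -= dmu; mu = mu_new; }

    // loci
    for (int j = 0; j < m; ++j) {
      const double* zj = Z.colptr(j);
      const double cj = zwz[j];
      double r = 0.0;
      for (int i = 0; i < n; ++i) r += wv[i] * zj[i] * e[i];
      r += cj * u[j];

      const double s2 = bayesB ? sigma2_j[j] : sigma2_u;
      int del = 1;
      if (!always_in) {
        const double v0 = cj * sigma2_e;
        const double v1 = cj * cj * s2 + v0;
        const double logodds = log_prior_odds +
          0.5 * (std::log(v0 / v1) + r * r * (1.0 / v0 - 1.0 / v1));
        double pj;
        if (logodds > 35.0) pj = 1.0;
        else if (logodds < -35.0) pj = 0.0;
        else pj = 1.0 / (1.0 + std::exp(-logodds));
        del = (R::unif_rand() < pj) ? 1 : 0;
      }

      double u_new = 0.0;
      if (del) {
        const double lhs = cj + sigma2_e / s2;
        u_new = r / lhs + R::norm_rand() * std::sqrt(sigma2_e / lhs);
      }
      const double diff = u_new - u[j];
      if (diff != 0.0) {
        for (int i = 0; i < n; ++i) e[i] -= zj[i] * diff;
        u[j] = u_new;
      }

      if (bayesB && !fix_var) {
        sigma2_j[j] = del
          ? (nu_u * S_u + u[j] * u[j]) / R::rchisq(nu_u + 1.0)
          : rscinvchisq(nu_u, S_u);
      }
    }

    if (!bayesB && !fix_var) {
      int m_in = 0; double ss = 0.0;
      for (int j = 0; j < m; ++j) {
        if (u[j] != 0.0) { ++m_in; ss += u[j] * u[j]; }
      }
      sigma2_u = (nu_u * S_u + ss) / R::rchisq(nu_u + m_in);
    }
    if (!fix_var) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += wv[i] * e[i] * e[i];
      sigma2_e = (nu_e * S_e + sse) / R::rchisq(nu_e + n);
    }

    if (it > burn_in) {
      ++n_post;
      u_sum += u;
      for (int j = 0; j < m; ++j) if (u[j] != 0.0) incl[j] += 1.0;
      mu_sum += mu; sig_u_sum += sigma2_u; sig_e_sum += sigma2_e;
      if ((it - burn_in) % thin == 0 && kept < n_keep) {
        U.row(kept) = u.t();
        keep_sigma2_u[kept] = sigma2_u;
        keep_sigma2_e[kept] = sigma2_e;
        keep_mu[kept] = mu;
        ++kept;
      }
    }
  }

  return List::create(
    _["effect"] = u_sum / n_post,
    _["inclusion_prob"] = incl / n_post,
    _["mu"] = mu_sum / n_post,
    _["post_mean_sigma2_u"] = sig_u_sum / n_post,
    _["post_mean_sigma2_e"] = sig_e_sum / n_post,
    _["samples_u"] = U,
    _["samples_sigma2_u"] = keep_sigma2_u,
    _["samples_sigma2_e"] = keep_sigma2_e,
    _["samples_mu"] = keep_mu,
    _["n_samples"] = kept
  );
}
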