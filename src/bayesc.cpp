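// Gibbs sampler for BayesC-pi whole-genome regression:
//   y = 1*mu + W b + e,  b_j = 0 with prob pi, N(0, s2b) otherwise,
//   pi ~ Beta(1, 1) (optionally fixed), s2b and s2e scaled-inv-chi^2.
// Uses R's RNG so chains are reproducible via set.seed() on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List bayesc_gibbs_cpp(const arma::mat& W, const arma::vec& y,
                      int n_iter, int burn_in,
                      double df_b, double S_b, double df_e, double S_e,
                      double pi_init, bool estimate_pi) {
  const int n = W.n_rows;
  const int m = W.n_cols;
  arma::vec wtw(m);
  for (int j = 0; j < m; ++j) wtw[j] = arma::dot(W.col(j), W.col(j));

  double mu = arma::mean(y);
  arma::vec b(m, arma::fill::zeros);
  std::vector<char> in_model(m, 0);
  double pi = pi_init;            // probability of a ZERO effect
  double s2b = S_b / (df_b + 2.0);
  double s2e = S_e / (df_e + 2.0);
  arma::vec e = y - mu;

  const int n_keep = n_iter - burn_in;
  arma::vec b_sum(m, arma::fill::zeros);
  double mu_sum = 0.0, pi_sum = 0.0, s2b_sum = 0.0, s2e_sum = 0.0;
  arma::vec s2e_chain(n_keep), pi_chain(n_keep);

  for (int it = 0; it < n_iter; ++it) {
    // intercept
    double mu_new = R::rnorm(mu + arma::mean(e), std::sqrt(s2e / n));
    e -= (mu_new - mu);
    mu = mu_new;

    // marker effects with spike-and-slab indicator
    int k_in = 0;
    double ssb = 0.0;
    double* ep = e.memptr();
    for (int j = 0; j < m; ++j) {
      if (wtw[j] <= 0.0) { b[j] = 0.0; in_model[j] = 0; continue; }
      const double b_old = b[j];
      const double* wj = W.colptr(j);
      double dot = 0.0;
      for (int i = 0; i < n; ++i) dot += wj[i] * ep[i];
      double z = dot + wtw[j] * b_old;
      const double C = wtw[j] + s2e / s2b;
      const double logBF = 0.5 * z * z / (s2e * C)
                         - 0.5 * std::log(C * s2b / s2e);
      double log_odds;
      if (pi <= 0.0)      log_odds = R_PosInf;
      else if (pi >= 1.0) log_odds = R_NegInf;
      else                log_odds = std::log((1.0 - pi) / pi) + logBF;
      double p_in;
      if (log_odds > 35.0)       p_in = 1.0;
      else if (log_odds < -35.0) p_in = 0.0;
      else                       p_in = 1.0 / (1.0 + std::exp(-log_odds));
      double b_new = 0.0;
      char inc = (unif_rand() < p_in) ? 1 : 0;
      if (inc) {
        b_new = R::rnorm(z / C, std::sqrt(s2e / C));
        ++k_in;
        ssb += b_new * b_new;
      }
      if (b_new != b_old) {
        const double diff = b_old - b_new;
        for (int i = 0; i < n; ++i) ep[i] += wj[i] * diff;
      }
      b[j] = b_new;
      in_model[j] = inc;
    }

    // variance components
    s2b = (S_b + ssb) / R::rchisq(df_b + k_in);
    s2e = (S_e + arma::dot(e, e)) / R::rchisq(df_e + n);

    // mixture proportion
    if (estimate_pi) pi = R::rbeta(1.0 + (m - k_in), 1.0 + k_in);

    if (it >= burn_in) {
      const int idx = it - burn_in;
      b_sum += b;
      mu_sum += mu;
      pi_sum += pi;
      s2b_sum += s2b;
      s2e_sum += s2e;
      s2e_chain[idx] = s2e;
      pi_chain[idx] = pi;
    }
  }

  return List::create(
    _["mu_mean"] = mu_sum / n_keep,
    _["b_mean"] = b_sum / n_keep,
    _["pi_mean"] = pi_sum / n_keep,
    _["s2b_mean"] = s2b_sum / n_keep,
    _["s2e_mean"] = s2e_sum / n_keep,
    _["s2e_chain"] = s2e_chain,
    _["pi_chain"] = pi_chain);
}
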