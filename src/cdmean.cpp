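// Stochastic exchange search for CDmean training-set selection.
// Maintains M = (lambda * A^-1 + diag(sel))^-1 under Sherman-Morrison
// rank-one updates; the intercept projector's rank-one term and the
// candidate-average contrast are applied analytically, so evaluating a
// proposal costs O(N^2). Uses R's RNG (seeded on the R side).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// mean CD over targets given M (inverse of G0), selection, and contrast
// precomputations. diagA = diag(Ar); Am_bar = Ar * mbar; mAm = mbar'Ar mbar.
static double cd_mean_obj(const arma::mat& M, const arma::uvec& sel_idx,
                          const arma::uvec& targets, const arma::vec& mbar,
                          const arma::vec& diagA, const arma::vec& Am_bar,
                          double mAm, double lambda) {
  const double n_t = (double)sel_idx.n_elem;
  arma::vec u = arma::sum(M.cols(sel_idx), 1);
  double s = n_t - arma::accu(u.elem(sel_idx));
  arma::vec vm = M * mbar;
  double um = arma::dot(u, mbar);
  double mGm = arma::dot(mbar, vm) + um * um / s;
  double acc = 0.0;
  for (arma::uword k = 0; k < targets.n_elem; ++k) {
    arma::uword t = targets[k];
    double diagG = M(t, t) + u[t] * u[t] / s;
    double Gm_t = vm[t] + u[t] * um / s;
    double num = (diagA[t] - lambda * diagG)
               - 2.0 * (Am_bar[t] - lambda * Gm_t)
               + (mAm - lambda * mGm);
    double den = diagA[t] - 2.0 * Am_bar[t] + mAm;
    acc += num / den;
  }
  return acc / (double)targets.n_elem;
}

// [[Rcpp::export]]
List cdmean_search_cpp(const arma::mat& Ar, const arma::mat& lamAinv,
                       arma::uvec sel, const arma::uvec& cand_idx,
                       const arma::uvec& fixed_targets, bool targeted,
                       const arma::vec& mbar, double lambda,
                       int max_stall, int refresh_every) {
  const arma::uword N = Ar.n_rows;
  const arma::vec diagA = Ar.diag();
  const arma::vec Am_bar = Ar * mbar;
  const double mAm = arma::dot(mbar, Am_bar);

  std::vector<char> in_sel(N, 0);
  for (arma::uword k = 0; k < sel.n_elem; ++k) in_sel[sel[k]] = 1;
  std::vector<arma::uword> pool; // non-selected candidates
  for (arma::uword k = 0; k < cand_idx.n_elem; ++k) {
    if (!in_sel[cand_idx[k]]) pool.push_back(cand_idx[k]);
  }

  arma::mat G0 = lamAinv;
  for (arma::uword k = 0; k < sel.n_elem; ++k) G0(sel[k], sel[k]) += 1.0;
  arma::mat M = arma::inv_sympd(G0);

  auto targets_now = [&](void) -> arma::uvec {
    if (targeted) return fixed_targets;
    return arma::uvec(pool);
  };

  double obj = cd_mean_obj(M, sel, targets_now(), mbar, diagA, Am_bar, mAm,
                           lambda);
  const double obj0 = obj;
  int stall = 0, accepts = 0;
  arma::mat M2(N, N);
  arma::uvec sel2;

  while (stall < max_stall) {
    const arma::uword ii = (arma::uword)(unif_rand() * sel.n_elem);
    const arma::uword jj = (arma::uword)(unif_rand() * pool.size());
    const arma::uword i = sel[ii];
    const arma::uword j = pool[jj];

    // remove i: (G0 - e_i e_i')^-1 = M + M[,i] M[i,]' / (1 - M[i,i])
    M2 = M + (M.col(i) * M.row(i)) / (1.0 - M(i, i));
    // add j
    M2 -= (M2.col(j) * M2.row(j)) / (1.0 + M2(j, j));

    sel2 = sel;
    sel2[ii] = j;
    pool[jj] = i; // evaluate with the pool in its post-swap state

    double obj2 = cd_mean_obj(M2, sel2, targets_now(), mbar, diagA, Am_bar,
                              mAm, lambda);
    if (obj2 > obj + 1e-12) {
      sel = sel2;
      M = M2;
      obj = obj2;
      stall = 0;
      ++accepts;
      in_sel[i] = 0;
      in_sel[j] = 1;
      if (refresh_every > 0 && accepts % refresh_every == 0) {
        G0 = lamAinv;
        for (arma::uword k = 0; k < sel.n_elem; ++k) G0(sel[k], sel[k]) += 1.0;
        M = arma::inv_sympd(G0);
      }
    } else {
      pool[jj] = j; // undo
      ++stall;
    }
  }
  return List::create(_["sel"] = sel, _["obj"] = obj, _["obj0"] = obj0,
                      _["accepts"] = accepts);
}
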