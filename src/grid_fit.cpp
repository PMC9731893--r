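#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive grid-search ML fit of one session under one model.
//
// Model codes: 1 = M_ab (single alpha, kappa fixed 0), 2 = M_abk (single
// alpha), 3 = M_a2bk (alpha_rew x alpha_nonrew). Axes are supplied by R in
// ascending order; for M_ab the kappa axis must be the single value 0.
//
// The Q trajectory depends only on the alpha(s), choices and rewards, so it
// is computed once per alpha combination. With d_t = Q(L)-Q(R) before the
// choice, sigma_t = +1 if L chosen else -1, and s_t the previous-choice
// indicator difference (L_{t-1} - R_{t-1}), the per-trial negative
// log-probability of the observed choice is
//   log(1 + exp(-sigma_t * (d_t/beta + kappa * s_t)))
//     = log(1 + exp(-a_t/beta) * c_t),   a_t = sigma_t d_t,
// where c_t = exp(-kappa), exp(kappa) or 1 depending on sigma_t s_t.
// exp(-a_t/beta) is hoisted out of the kappa loop, and the sum of log1p
// terms is accumulated as a running product with overflow flushing, leaving
// one multiply per (trial, beta, kappa) in the hot loop. |a_t/beta| <= 200
// at the stated bounds, so individual factors never overflow a double.
//
// Ties are broken by first occurrence in lexicographic grid order
// (alpha_rew, alpha_nonrew, alpha, beta, kappa; values ascending), which is
// exactly the loop nesting below with a strict '>' improvement test.
// [[Rcpp::export]]
List cpp_grid_fit(IntegerVector chosen_left, IntegerVector reward,
                  int model,
                  NumericVector alpha_axis, NumericVector beta_axis,
                  NumericVector kappa_axis, double q0) {
  const int n = chosen_left.size();
  if (n == 0) stop("empty session");
  const int nA = alpha_axis.size(), nB = beta_axis.size(),
            nK = kappa_axis.size();
  const bool tied = (model != 3);

  std::vector<double> a(n), w(n);
  std::vector<int> g(n);
  double best_ll = R_NegInf;
  double best_a1 = NA_REAL, best_a2 = NA_REAL, best_b = NA_REAL,
         best_k = NA_REAL;

  for (int i1 = 0; i1 < nA; ++i1) {
    const double a1 = alpha_axis[i1];  // alpha_rew (or the single alpha)
    for (int i2 = 0; i2 < (tied ? 1 : nA); ++i2) {
      const double a2 = tied ? a1 : alpha_axis[i2];  // alpha_nonrew
      // Q trajectory for this alpha combination
      double qL = q0, qR = q0;
      int prev = 0;
      for (int t = 0; t < n; ++t) {
        const int sigma = chosen_left[t] ? 1 : -1;
        a[t] = sigma * (qL - qR);
        g[t] = sigma * prev;
        const double alpha = reward[t] ? a1 : a2;
        if (chosen_left[t]) qL += alpha * (reward[t] - qL);
        else                qR += alpha * (reward[t] - qR);
        prev = sigma;
      }
      for (int ib = 0; ib < nB; ++ib) {
        const double inv_beta = 1.0 / beta_axis[ib];
        for (int t = 0; t < n; ++t) w[t] = std::exp(-a[t] * inv_beta);
        for (int ik = 0; ik < nK; ++ik) {
          const double kappa = kappa_axis[ik];
          const double cp = std::exp(-kappa), cm = std::exp(kappa);
          double logsum = 0.0, prod = 1.0;
          for (int t = 0; t < n; ++t) {
            const double c = g[t] > 0 ? cp : (g[t] < 0 ? cm : 1.0);
            prod *= 1.0 + w[t] * c;
            if (prod > 1e280) { logsum += std::log(prod); prod = 1.0; }
          }
          const double ll = -(logsum + std::log(prod));
          if (ll > best_ll) {
            best_ll = ll;
            best_a1 = a1; best_a2 = a2;
            best_b = beta_axis[ib]; best_k = kappa;
          }
        }
      }
    }
  }
  return List::create(_["loglik"] = best_ll,
                      _["alpha_rew"] = best_a1, _["alpha_nonrew"] = best_a2,
                      _["beta"] = best_b, _["kappa"] = best_k,
                      _["n_trials"] = n);
}
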