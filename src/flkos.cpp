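// FLkOS iteration core: guided sampling over the sorted squared residuals.
// Kept in C++ because windowed fitting calls this thousands of times per
// detector frame; everything else in the package is vectorized R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec ols_coef(const arma::mat& X, const arma::vec& y,
                          const arma::uvec& idx) {
  arma::mat Xs = X.rows(idx);
  arma::vec ys = y.elem(idx);
  arma::vec coef;
  bool ok = arma::solve(coef, Xs, ys, arma::solve_opts::no_approx);
  if (!ok) coef = arma::pinv(Xs) * ys;  // degenerate subset: minimum-norm LS
  return coef;
}

// X: N x p design, y: N responses, subset0: 0-based initial subset indices,
// k: 1-based rank of the assumed structure size, s_sched: subset size per
// iteration (certain_ratio schedule, already converted to counts).
// Iterates: OLS on subset -> squared residuals for all points -> stable sort
// -> next subset = ranks [k - s + 1, k]. Tracks the subset whose fit gave the
// lowest kth sorted squared residual, stops early when the subset repeats,
// and refits on the best subset.
// [[Rcpp::export]]
List cpp_flkos(const arma::mat& X, const arma::vec& y,
               const arma::uvec& subset0, const int k,
               const arma::ivec& s_sched) {
  const int n_iter = s_sched.n_elem;
  arma::uvec cur = subset0;
  arma::uvec prev_set = arma::sort(cur);
  arma::uvec best_subset = cur;
  double best_kth = arma::datum::inf;
  int iters_run = 0;

  for (int it = 0; it < n_iter; ++it) {
    ++iters_run;
    arma::vec coef = ols_coef(X, y, cur);
    arma::vec r2 = arma::square(y - X * coef);
    arma::uvec ord = arma::stable_sort_index(r2, "ascend");
    double kth = r2(ord(k - 1));
    if (kth < best_kth) {
      best_kth = kth;
      best_subset = cur;
    }
    int s = s_sched(it);
    arma::uvec nxt = ord.subvec(k - s, k - 1);
    arma::uvec nxt_set = arma::sort(nxt);
    if (nxt_set.n_elem == prev_set.n_elem &&
        arma::all(nxt_set == prev_set)) {
      break;  // rank-set repeated: converged
    }
    prev_set = nxt_set;
    cur = nxt;
  }

  arma::vec coef = ols_coef(X, y, best_subset);
  arma::vec resid = y - X * coef;
  return List::create(_["coef"] = coef,
                      _["residuals"] = resid,
                      _["best_kth_r2"] = best_kth,
                      _["iterations"] = iters_run);
}
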