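// Multiplicative-update NMF under the Kullback-Leibler divergence
// (Brunet-style updates). The hot loop lives here; all validation,
// seeding and bookkeeping happen on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& A, const mat& V) {
  // D(A || V) = sum( a*log(a/v) - a + v ), with a=0 terms contributing v
  double d = 0.0;
  const double* a = A.memptr();
  const double* v = V.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i) {
    double ai = a[i], vi = v[i];
    if (ai > 0.0) d += ai * std::log(ai / vi) - ai + vi;
    else d += vi;
  }
  return d;
}

// [[Rcpp::export]]
Rcpp::List nmf_brunet_cpp(const arma::mat& A, arma::mat W, arma::mat H,
                          int max_iter, int check_interval, int stable_checks,
                          bool track_objective) {
  const double eps = 1e-16;
  const uword M = A.n_cols;

  uvec labels(M, fill::zeros), prev_labels(M, fill::zeros);
  int stable = 0, iter = 0;
  bool converged = false;
  std::vector<double> obj_hist;
  std::vector<int> obj_iter;

  mat V = W * H;
  for (iter = 1; iter <= max_iter; ++iter) {
    // H update: H <- H .* (W' (A ./ WH)) ./ (W' 1)
    mat P = A / (V + eps);
    rowvec wsum = sum(W, 0);           // 1 x k
    H = H % (W.t() * P);
    H.each_col() /= (wsum.t() + eps);

    // W update with refreshed quotient
    V = W * H;
    P = A / (V + eps);
    colvec hsum = sum(H, 1);           // k x 1
    W = W % (P * H.t());
    W.each_row() /= (hsum.t() + eps);
    V = W * H;

    if (iter % check_interval == 0 || iter == max_iter) {
      if (track_objective) {
        obj_hist.push_back(kl_div(A, V + eps));
        obj_iter.push_back(iter);
      }
      for (uword j = 0; j < M; ++j) labels(j) = H.col(j).index_max();
      if (iter > check_interval && all(labels == prev_labels)) {
        if (++stable >= stable_checks) { converged = true; break; }
      } else {
        stable = 0;
      }
      prev_labels = labels;
    }
  }
  if (iter > max_iter) iter = max_iter;

  double objective = kl_div(A, V + eps);
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective") = objective,
    Rcpp::Named("objective_history") = obj_hist,
    Rcpp::Named("objective_iterations") = obj_iter,
    Rcpp::Named("n_iter") = iter,
    Rcpp::Named("converged") = converged);
}
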