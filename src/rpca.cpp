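// Hot loop of the Ranking-PCA greedy forward search: score each candidate
// variable by the leave-one-out non-error rate of an equal-prior LDA run on
// the top principal components of the tentatively extended variable set.
//
// PCA is done in sample space: with X column-centered and G = X_S X_S' the
// n x n Gram matrix of the selected set S, adding candidate x is the rank-1
// update G + x x', and PC scores are U * diag(sqrt(lambda)) from the
// eigendecomposition of G. n is small (tens of samples), so each candidate
// costs one n x n eig_sym plus an O(n p^2) LOO sweep.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// LOO-NER of a two-class LDA (pooled covariance, equal priors) on scores S.
static double loo_ner(const mat& S, const uvec& y) {
  const uword n = S.n_rows, p = S.n_cols;
  const uvec idx0 = find(y == 0), idx1 = find(y == 1);
  const double n0 = idx0.n_elem, n1 = idx1.n_elem;
  rowvec sum0 = sum(S.rows(idx0), 0);
  rowvec sum1 = sum(S.rows(idx1), 0);
  rowvec m0 = sum0 / n0, m1 = sum1 / n1;

  // pooled within-class scatter
  mat W(p, p, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    rowvec d = S.row(i) - (y(i) == 0 ? m0 : m1);
    W += d.t() * d;
  }

  uword correct = 0;
  for (uword i = 0; i < n; ++i) {
    const bool in0 = (y(i) == 0);
    const double nc = in0 ? n0 : n1;
    if (nc < 2) continue;  // cannot leave out the lone member of a class
    rowvec mc = in0 ? m0 : m1;
    rowvec mo = in0 ? m1 : m0;
    rowvec mc_i = (in0 ? sum0 : sum1);
    mc_i = (mc_i - S.row(i)) / (nc - 1.0);
    rowvec d = S.row(i) - mc;
    mat Wi = W - (nc / (nc - 1.0)) * (d.t() * d);
    mat Sw = Wi / (double)(n - 3);  // n-1 obs, 2 classes
    Sw.diag() += 1e-10 * (trace(Sw) / p + 1e-12);  // ridge guard
    mat Swi;
    if (!inv_sympd(Swi, Sw)) Swi = pinv(Sw);
    rowvec dc = S.row(i) - mc_i;
    rowvec doo = S.row(i) - mo;
    double d2c = as_scalar(dc * Swi * dc.t());
    double d2o = as_scalar(doo * Swi * doo.t());
    if (d2c <= d2o) ++correct;
  }
  return 100.0 * (double)correct / (double)n;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_rpca_score(const arma::mat& X,
                                   const arma::uvec& y,
                                   const arma::mat& Gsel,
                                   const arma::uvec& cand,
                                   const int max_pcs) {
  const uword n = X.n_rows;
  Rcpp::NumericVector out(cand.n_elem);
  const double tol = 1e-9;
  for (uword k = 0; k < cand.n_elem; ++k) {
    vec x = X.col(cand(k));  // cand is 0-based
    mat G = Gsel + x * x.t();
    vec eigval;
    mat eigvec;
    if (!eig_sym(eigval, eigvec, G)) { out[k] = NA_REAL; continue; }
    // eigenvalues ascending: take the top max_pcs above tolerance
    const double thresh = tol * std::max(eigval.max(), 1.0);
    uvec keep = find(eigval > thresh);
    if (keep.n_elem == 0) { out[k] = 0.0; continue; }
    const uword p = std::min<uword>(max_pcs, keep.n_elem);
    mat S(n, p);
    for (uword j = 0; j < p; ++j) {
      const uword col = eigvec.n_cols - 1 - j;  // largest first
      S.col(j) = eigvec.col(col) * std::sqrt(eigval(col));
    }
    out[k] = loo_ner(S, y);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_loo_ner(const arma::mat& S, const arma::uvec& y) {
  return loo_ner(S, y);
}
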