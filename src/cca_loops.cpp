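// Hot loops for canonical correlation analysis: per-fold fits for
// cross-validated R2 and the trial-shuffle null distribution.
// Conventions: observations in rows, units in columns; inputs need not be
// centered (each fold centers by its own training means). Columns whose
// training-fold standard deviation is ~0 are dropped from that fit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct CCAFit {
  vec cor;
  mat A, B;        // weight matrices for kept columns
  uvec keepA, keepB;
  rowvec muA, muB;
  bool ok;
};

static CCAFit cca_fit(const mat& X0, const mat& Y0) {
  CCAFit f; f.ok = false;
  rowvec muA = mean(X0, 0), muB = mean(Y0, 0);
  mat X = X0.each_row() - muA;
  mat Y = Y0.each_row() - muB;
  rowvec sdA = stddev(X, 0, 0), sdB = stddev(Y, 0, 0);
  f.keepA = find(sdA > 1e-10);
  f.keepB = find(sdB > 1e-10);
  if (f.keepA.n_elem == 0 || f.keepB.n_elem == 0) return f;
  X = X.cols(f.keepA); Y = Y.cols(f.keepB);
  double n1 = X.n_rows - 1.0;
  mat Sxx = X.t() * X / n1, Syy = Y.t() * Y / n1, Sxy = X.t() * Y / n1;
  Sxx.diag() += 1e-12 * trace(Sxx) / Sxx.n_rows + 1e-300;
  Syy.diag() += 1e-12 * trace(Syy) / Syy.n_rows + 1e-300;
  mat Rx, Ry;
  if (!chol(Rx, Sxx) || !chol(Ry, Syy)) return f;
  // Z2 = Rx^{-T} Sxy Ry^{-1}
  mat Z = solve(trimatl(Rx.t()), Sxy);
  mat Z2 = solve(trimatl(Ry.t()), Z.t()).t();
  mat U, V; vec s;
  if (!svd_econ(U, s, V, Z2)) return f;
  f.cor = clamp(s, 0.0, 1.0);
  f.A = solve(trimatu(Rx), U);
  f.B = solve(trimatu(Ry), V);
  f.muA = muA; f.muB = muB;
  f.ok = true;
  return f;
}

static double r2_pair(const vec& a, const vec& b) {
  double sa = stddev(a), sb = stddev(b);
  if (sa < 1e-300 || sb < 1e-300) return 0.0;
  double r = as_scalar(cor(a, b));
  return r * r;
}

// Per-fold cross-validated R2 per CV. foldId is 1-based; returns a
// folds x k matrix (k = smallest CV count over folds, columns beyond a
// fold's k are NA).
// [[Rcpp::export]]
arma::mat cpp_cv_r2(const arma::mat& XA, const arma::mat& XB,
                    const arma::ivec& foldId, int nFolds) {
  int kmax = std::min(XA.n_cols, XB.n_cols);
  mat out(nFolds, kmax); out.fill(datum::nan);
  for (int f = 1; f <= nFolds; ++f) {
    uvec te = find(foldId == f), tr = find(foldId != f);
    if (te.n_elem < 3 || tr.n_elem <= std::max(XA.n_cols, XB.n_cols)) continue;
    CCAFit fit = cca_fit(XA.rows(tr), XB.rows(tr));
    if (!fit.ok) continue;
    mat Xte = XA.rows(te); Xte.each_row() -= fit.muA;
    mat Yte = XB.rows(te); Yte.each_row() -= fit.muB;
    mat PA = Xte.cols(fit.keepA) * fit.A;
    mat PB = Yte.cols(fit.keepB) * fit.B;
    int k = std::min(PA.n_cols, PB.n_cols);
    for (int j = 0; j < k && j < kmax; ++j)
      out(f - 1, j) = r2_pair(PA.col(j), PB.col(j));
  }
  return out;
}

// Trial-shuffle null for CV significance. XA stays in trial order; XB's
// trial blocks (all of length binsPerTrial) are re-ordered by each row of
// perms (1-based trial indices). Statistic per shuffle: mean cross-validated
// top-CV R2 over folds (crossval = true) or the training-fit top canonical
// correlation squared (crossval = false).
// [[Rcpp::export]]
arma::vec cpp_shuffle_null(const arma::mat& XA, const arma::mat& XB,
                           const arma::imat& perms, int binsPerTrial,
                           const arma::ivec& foldId, int nFolds,
                           bool crossval) {
  int nShuf = perms.n_rows, nTrials = perms.n_cols;
  vec out(nShuf, fill::value(datum::nan));
  uvec rowOrder(nTrials * binsPerTrial);
  for (int s = 0; s < nShuf; ++s) {
    for (int t = 0; t < nTrials; ++t) {
      int src = perms(s, t) - 1;
      for (int b = 0; b < binsPerTrial; ++b)
        rowOrder[t * binsPerTrial + b] = src * binsPerTrial + b;
    }
    mat XBs = XB.rows(rowOrder);
    if (crossval) {
      // null statistic: the best cross-validated R2 over all CVs of the
      // shuffled fit, so that "any observed CV beats the null's 95th
      // percentile" is exchangeable with the observed family maximum
      mat r2 = cpp_cv_r2(XA, XBs, foldId, nFolds);
      double best = datum::nan;
      for (unsigned j = 0; j < r2.n_cols; ++j) {
        vec c = r2.col(j);
        uvec f = find_finite(c);
        if (f.n_elem == 0) continue;
        double m = mean(c.elem(f));
        if (!std::isfinite(best) || m > best) best = m;
      }
      out[s] = best;
    } else {
      CCAFit fit = cca_fit(XA, XBs);
      if (fit.ok) out[s] = fit.cor[0] * fit.cor[0];
    }
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
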