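// Batch evaluation of Gaussian information measures over variable tuples,
// and histogram mutual information with permutation nulls. These are the
// inner loops of the tuple scans and the pairwise significance maps; all
// determinants go through Cholesky so non-positive-definite submatrices are
// detected (returned as NA) rather than producing NaN downstream.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Small fast deterministic RNG (splitmix64) for permutation shuffles;
// platform-independent and cheap enough for millions of Fisher-Yates swaps.
static inline uint64_t splitmix64(uint64_t& s) {
  s += 0x9e3779b97f4a7c15ULL;
  uint64_t z = s;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
struct FastRng {
  uint64_t s;
  explicit FastRng(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) splitmix64(s);
  }
  // uniform integer in [0, n), Lemire's multiply-shift mapping
  inline uint32_t bounded(uint32_t n) {
    uint32_t r = (uint32_t)(splitmix64(s) >> 32);
    return (uint32_t)(((uint64_t)r * n) >> 32);
  }
};
static inline void shuffle_ints(std::vector<int>& v, FastRng& rng) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)rng.bounded((uint32_t)(i + 1));
    std::swap(v[i], v[j]);
  }
}

// log|A| via Cholesky; false if A is not (numerically) positive definite.
// Exactly collinear variables can pass floating-point Cholesky with a tiny
// positive pivot, so pivots below relative tolerance count as singular.
static bool chol_logdet(const arma::mat& A, double& ld) {
  arma::mat R;
  if (!arma::chol(R, A)) return false;
  double mn = R.diag().min();
  if (mn * mn < 1e-12 * A.diag().max()) return false;
  ld = 2.0 * arma::accu(arma::log(R.diag()));
  return std::isfinite(ld);
}

// O-information of each tuple (column of `tuples`, 1-based indices into S):
//   O = 1/2 * [ (k-2) log|S_t| + sum_i log s_ii - sum_i log|S_{t,-i}| ]
// [[Rcpp::export]]
NumericVector oinfo_batch_cpp(const arma::mat& S, const IntegerMatrix& tuples) {
  const int k = tuples.nrow(), m = tuples.ncol();
  NumericVector out(m);
  arma::uvec idx(k);
  for (int j = 0; j < m; ++j) {
    for (int r = 0; r < k; ++r) idx[r] = (arma::uword)(tuples(r, j) - 1);
    arma::mat sub = S.submat(idx, idx);
    double ld;
    if (!chol_logdet(sub, ld)) { out[j] = NA_REAL; continue; }
    double acc = (k - 2) * ld;
    bool ok = true;
    arma::uvec keep(k - 1);
    for (int i = 0; i < k && ok; ++i) {
      double sii = sub(i, i);
      if (sii <= 0.0) { ok = false; break; }
      acc += std::log(sii);
      int c = 0;
      for (int r = 0; r < k; ++r) if (r != i) keep[c++] = (arma::uword)r;
      arma::mat minor_ = sub.submat(keep, keep);
      double ldm;
      if (!chol_logdet(minor_, ldm)) { ok = false; break; }
      acc -= ldm;
    }
    out[j] = ok ? 0.5 * acc : NA_REAL;
  }
  return out;
}

// RSI (printed convention, i.e. I(S;Y) - sum_i I(X_i;Y)) for each predictor
// tuple against target column `target` (1-based).
// [[Rcpp::export]]
NumericVector rsi_batch_cpp(const arma::mat& S, const IntegerMatrix& tuples,
                            const int target) {
  const int k = tuples.nrow(), m = tuples.ncol();
  const arma::uword t = (arma::uword)(target - 1);
  const double syy = S(t, t);
  NumericVector out(m);
  if (syy <= 0.0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  arma::uvec idx(k), tv(1); tv[0] = t;
  for (int j = 0; j < m; ++j) {
    for (int r = 0; r < k; ++r) idx[r] = (arma::uword)(tuples(r, j) - 1);
    arma::mat sub = S.submat(idx, idx);
    arma::vec sty = S.submat(idx, tv);
    arma::mat cond = sub - (sty * sty.t()) / syy;
    double ldS, ldC;
    if (!chol_logdet(sub, ldS) || !chol_logdet(cond, ldC)) {
      out[j] = NA_REAL; continue;
    }
    double i_joint = 0.5 * (ldS - ldC);
    double i_sum = 0.0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      double sii = sub(i, i);
      double rho2 = (sty[i] * sty[i]) / (sii * syy);
      if (sii <= 0.0 || rho2 >= 1.0) { ok = false; break; }
      i_sum += -0.5 * std::log1p(-rho2);
    }
    out[j] = ok ? (i_joint - i_sum) : NA_REAL;
  }
  return out;
}

static double mi_from_bins(const int* bx, const int* by, const int n,
                           const int nbx, const int nby,
                           std::vector<int>& joint, std::vector<int>& cx,
                           std::vector<int>& cy) {
  std::fill(joint.begin(), joint.end(), 0);
  std::fill(cx.begin(), cx.end(), 0);
  std::fill(cy.begin(), cy.end(), 0);
  for (int i = 0; i < n; ++i) {
    ++joint[(bx[i] - 1) * nby + (by[i] - 1)];
    ++cx[bx[i] - 1];
    ++cy[by[i] - 1];
  }
  double mi = 0.0, dn = (double)n;
  for (int a = 0; a < nbx; ++a) {
    if (cx[a] == 0) continue;
    for (int b = 0; b < nby; ++b) {
      int c = joint[a * nby + b];
      if (c > 0)
        mi += (c / dn) * std::log(c * dn / ((double)cx[a] * (double)cy[b]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;
}

// Plug-in MI (nats) of two pre-binned vectors (1-based bin indices).
// [[Rcpp::export]]
double hist_mi_cpp(const IntegerVector& bx, const IntegerVector& by,
                   const int nbx, const int nby) {
  const int n = bx.size();
  std::vector<int> joint(nbx * nby), cx(nbx), cy(nby);
  return mi_from_bins(bx.begin(), by.begin(), n, nbx, nby, joint, cx, cy);
}

// Permutation p-value for MI of two pre-binned vectors: shuffles `by`,
// add-one p = (1 + #{MI_perm >= MI_obs}) / (1 + n_perm). Deterministic for a
// given seed (own mt19937, independent of R's RNG).
// [[Rcpp::export]]
List perm_test_mi_cpp(const IntegerVector& bx, const IntegerVector& by,
                      const int nbx, const int nby, const int n_perm,
                      const int seed) {
  const int n = bx.size();
  std::vector<int> joint(nbx * nby), cx(nbx), cy(nby);
  double obs = mi_from_bins(bx.begin(), by.begin(), n, nbx, nby, joint, cx, cy);
  std::vector<int> perm(by.begin(), by.end());
  FastRng eng((uint64_t)(uint32_t)seed * 2654435761ULL + 0x9e3779b9ULL);
  int ge = 0;
  for (int p = 0; p < n_perm; ++p) {
    shuffle_ints(perm, eng);
    double mi = mi_from_bins(bx.begin(), perm.data(), n, nbx, nby, joint, cx, cy);
    if (mi >= obs - 1e-15) ++ge;
  }
  return List::create(_["mi"] = obs,
                      _["p"] = (1.0 + ge) / (1.0 + n_perm));
}

// All-pairs MI + permutation p-values. XB: n x p matrix of 1-based bin
// indices. If YB has columns, tests the rectangular XB-column x YB-column
// map; otherwise all unordered pairs within XB. Each pair uses an engine
// seeded from (seed, i, j) so results do not depend on evaluation order.
// [[Rcpp::export]]
List mi_perm_pairs_cpp(const IntegerMatrix& XB, const IntegerVector& nbX,
                       const IntegerMatrix& YB, const IntegerVector& nbY,
                       const int n_perm, const int seed) {
  const int n = XB.nrow(), p = XB.ncol();
  const bool cross = YB.ncol() > 0;
  const int q = cross ? YB.ncol() : p;
  NumericMatrix mi(p, q), pv(p, q);
  std::fill(pv.begin(), pv.end(), 1.0);
  int maxb = 2;
  for (int i = 0; i < nbX.size(); ++i) maxb = std::max(maxb, nbX[i]);
  for (int i = 0; i < nbY.size(); ++i) maxb = std::max(maxb, nbY[i]);
  std::vector<int> joint(maxb * maxb), cx(maxb), cy(maxb), perm(n);
  for (int i = 0; i < p; ++i) {
    const int jstart = cross ? 0 : i + 1;
    for (int j = jstart; j < q; ++j) {
      const int* bx = &XB(0, i);
      const int* by = cross ? &YB(0, j) : &XB(0, j);
      const int nbx = nbX[i], nby = cross ? nbY[j] : nbX[j];
      double obs = mi_from_bins(bx, by, n, nbx, nby, joint, cx, cy);
      FastRng eng((uint64_t)(uint32_t)seed * 2654435761ULL +
                  (uint64_t)(uint32_t)i * 65537ULL + (uint64_t)(uint32_t)j +
                  0x9e3779b9ULL);
      std::copy(by, by + n, perm.begin());
      int ge = 0;
      for (int r = 0; r < n_perm; ++r) {
        shuffle_ints(perm, eng);
        double m = mi_from_bins(bx, perm.data(), n, nbx, nby, joint, cx, cy);
        if (m >= obs - 1e-15) ++ge;
      }
      double pval = (1.0 + ge) / (1.0 + n_perm);
      mi(i, j) = obs; pv(i, j) = pval;
      if (!cross) { mi(j, i) = obs; pv(j, i) = pval; }
    }
  }
  if (!cross)
    for (int i = 0; i < p; ++i) { mi(i, i) = NA_REAL; pv(i, i) = NA_REAL; }
  return List::create(_["mi"] = mi, _["p"] = pv);
}
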