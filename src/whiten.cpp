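#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Whitening transform for a Brownian-motion covariance on a rooted binary
// tree, by Felsenstein pruning. Returns the independent-contrast
// representation of a data matrix: n-1 standardised contrast rows plus the
// scaled root-estimate row, so that crossprod(W_a, W_b) == a' V^-1 b, and
// the log determinant of V.
//
// Pagel's lambda is applied as the usual transform that rescales shared
// (off-diagonal) path lengths only: every branch is multiplied by lambda
// and each terminal branch is stretched by (1 - lambda) * tip depth, which
// leaves the diagonal of V (root-to-tip lengths) unchanged.
//
// edge    postorder edge matrix (1-based node ids, tips 1..nTip, root nTip+1)
// elen    per-edge lengths, already multiplied by any rate scalars
// tipdata nTip x p matrix, rows in tree tip-label order
// ridge   minimum admissible contrast variance; variances below it are
//         raised to it (used only for singular covariances, counted and
//         reported so callers can warn)
// [[Rcpp::export(name = ".whiten_bm")]]
List whiten_bm(IntegerMatrix edge, NumericVector elen, double lambda,
               int nTip, NumericMatrix tipdata, double ridge) {
  const int E = edge.nrow();
  const int p = tipdata.ncol();
  int ntot = 0;
  for (int e = 0; e < E; ++e) {
    if (edge(e, 0) > ntot) ntot = edge(e, 0);
    if (edge(e, 1) > ntot) ntot = edge(e, 1);
  }
  const int root = nTip + 1;

  // node depths: reverse postorder visits parents before children
  std::vector<double> depth(ntot + 1, 0.0);
  for (int e = E - 1; e >= 0; --e)
    depth[edge(e, 1)] = depth[edge(e, 0)] + elen[e];

  // lambda transform on branch lengths
  std::vector<double> len(E);
  for (int e = 0; e < E; ++e) {
    const int c = edge(e, 1);
    len[e] = lambda * elen[e];
    if (c <= nTip) len[e] += (1.0 - lambda) * depth[c];
  }

  std::vector<double> val((size_t)(ntot + 1) * p, 0.0);
  std::vector<double> extra(ntot + 1, 0.0);
  std::vector<double> pend_v(ntot + 1, 0.0);
  std::vector<int> pend_c(ntot + 1, -1);
  std::vector<int> pend_e(ntot + 1, -1);
  for (int i = 0; i < nTip; ++i)
    for (int j = 0; j < p; ++j) val[(size_t)(i + 1) * p + j] = tipdata(i, j);

  NumericMatrix W(nTip, p);
  double logdet = 0.0;
  int wrow = 0, nridge = 0;

  for (int e = 0; e < E; ++e) {
    const int u = edge(e, 0), c = edge(e, 1);
    const double v = len[e] + extra[c];
    if (pend_e[u] < 0) {
      pend_e[u] = e;
      pend_c[u] = c;
      pend_v[u] = v;
    } else {
      const int c1 = pend_c[u];
      double s = pend_v[u] + v;
      if (s < ridge) { s = ridge; ++nridge; }
      const double sq = std::sqrt(s);
      const double v1 = pend_v[u], v2 = v;
      for (int j = 0; j < p; ++j) {
        const double a = val[(size_t)c1 * p + j];
        const double b = val[(size_t)c * p + j];
        W(wrow, j) = (a - b) / sq;
        val[(size_t)u * p + j] = (v2 * a + v1 * b) / s;
      }
      logdet += std::log(s);
      extra[u] = v1 * v2 / s;
      pend_e[u] = -1;
      ++wrow;
    }
  }
  if (wrow != nTip - 1)
    stop("tree is not strictly bifurcating after preparation");

  double v0 = extra[root];
  if (v0 < ridge) { v0 = ridge; ++nridge; }
  NumericVector rootval(p);
  const double sq0 = std::sqrt(v0);
  for (int j = 0; j < p; ++j) {
    rootval[j] = val[(size_t)root * p + j];
    W(nTip - 1, j) = rootval[j] / sq0;
  }
  logdet += std::log(v0);

  return List::create(_["W"] = W, _["logdet"] = logdet,
                      _["root"] = rootval, _["root_var"] = v0,
                      _["n_ridge"] = nridge);
}
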