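#include <Rcpp.h>
using namespace Rcpp;

// Exact interventional Shapley attributions for a tree ensemble.
//
// For one explained row x, one background (reference) row r and one tree,
// every leaf defines an indicator game over the features split on along
// its path: the leaf is reached iff each split is satisfied by the value
// in play (x's if the feature is in the coalition, r's otherwise).
// Collapsing repeated splits per feature, a leaf is reached by coalition S
// iff S contains all features where only x is path-consistent (set A) and
// none where only r is (set B); features consistent for both are null
// players and leaves where some feature is consistent for neither are
// unreachable. The Shapley value of such an indicator game is closed-form:
//   i in A:  +v * (a-1)! b! / (a+b)!
//   i in B:  -v * a! (b-1)! / (a+b)!
// with a=|A|, b=|B| and leaf value v. Summing over leaves, trees and
// background rows (averaged) gives attributions satisfying
//   sum(phi) = f(x) - mean_r f(r)
// exactly, i.e. interventional TreeSHAP.

namespace {

struct TreeWalker {
  const IntegerVector& feature;   // -1 at leaves
  const NumericVector& threshold;
  const IntegerVector& yes;       // global node index
  const IntegerVector& no;
  const NumericVector& value;     // leaf value
  const double* x;
  const double* r;
  std::vector<int> seen, viox, vior;  // per-feature path state
  std::vector<int> path_feats;        // distinct features on current path
  std::vector<double> fact;
  double* phi;                        // per-feature accumulator

  TreeWalker(const IntegerVector& f, const NumericVector& t,
             const IntegerVector& y, const IntegerVector& n,
             const NumericVector& v, int n_feat)
      : feature(f), threshold(t), yes(y), no(n), value(v),
        x(nullptr), r(nullptr),
        seen(n_feat, 0), viox(n_feat, 0), vior(n_feat, 0) {
    fact.resize(65);
    fact[0] = 1.0;
    for (int i = 1; i <= 64; ++i) fact[i] = fact[i - 1] * i;
  }

  void leaf(double v) {
    int a = 0, b = 0;
    for (int j : path_feats) {
      if (viox[j] == 0 && vior[j] > 0) ++a;
      else if (vior[j] == 0 && viox[j] > 0) ++b;
    }
    if (a == 0 && b == 0) return;  // contributes equally to f(x) and f(r)
    double wa = (a > 0) ? v * fact[a - 1] * fact[b] / fact[a + b] : 0.0;
    double wb = (b > 0) ? v * fact[a] * fact[b - 1] / fact[a + b] : 0.0;
    for (int j : path_feats) {
      if (viox[j] == 0 && vior[j] > 0) phi[j] += wa;
      else if (vior[j] == 0 && viox[j] > 0) phi[j] -= wb;
    }
  }

  void descend(int node, int j, bool xv, bool rv) {
    // enter child where split violated flags xv (for x) / rv (for r)
    if (seen[j] == 0) path_feats.push_back(j);
    ++seen[j];
    if (xv) ++viox[j];
    if (rv) ++vior[j];
    if (!(viox[j] > 0 && vior[j] > 0)) walk(node);  // else unreachable
    if (xv) --viox[j];
    if (rv) --vior[j];
    if (--seen[j] == 0) path_feats.pop_back();
  }

  void walk(int node) {
    int j = feature[node];
    if (j < 0) { leaf(value[node]); return; }
    // xgboost routes on float32 values; match it exactly or rows whose
    // value coincides with a histogram cut point get misrouted
    float t = static_cast<float>(threshold[node]);
    bool xgoes = static_cast<float>(x[j]) < t;
    bool rgoes = static_cast<float>(r[j]) < t;
    descend(yes[node], j, !xgoes, !rgoes);
    descend(no[node], j, xgoes, rgoes);
  }
};

}  // namespace

// Double-precision ensemble evaluation (margin, without base score).
// Routing matches xgboost's float32 comparisons; leaf values are summed
// in double so that attribution additivity holds to numerical precision.
// [[Rcpp::export]]
NumericVector tree_predict_cpp(IntegerVector tree_root,
                               IntegerVector feature,
                               NumericVector threshold,
                               IntegerVector yes, IntegerVector no,
                               NumericVector value, NumericMatrix X) {
  const int n_rows = X.nrow();
  NumericVector out(n_rows);
  for (int i = 0; i < n_rows; ++i) {
    double acc = 0.0;
    for (int t = 0; t < tree_root.size(); ++t) {
      int node = tree_root[t];
      while (feature[node] >= 0) {
        float thr = static_cast<float>(threshold[node]);
        bool goes = static_cast<float>(X(i, feature[node])) < thr;
        node = goes ? yes[node] : no[node];
      }
      acc += value[node];
    }
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix treeshap_interventional_cpp(IntegerVector tree_root,
                                          IntegerVector feature,
                                          NumericVector threshold,
                                          IntegerVector yes, IntegerVector no,
                                          NumericVector value,
                                          NumericMatrix X, NumericMatrix R) {
  const int n_rows = X.nrow(), n_feat = X.ncol(), n_ref = R.nrow();
  if (R.ncol() != n_feat) stop("background has wrong number of columns");
  NumericMatrix phi(n_rows, n_feat);
  TreeWalker w(feature, threshold, yes, no, value, n_feat);

  std::vector<double> xrow(n_feat), rrow(n_feat), acc(n_feat);
  for (int i = 0; i < n_rows; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int j = 0; j < n_feat; ++j) xrow[j] = X(i, j);
    w.x = xrow.data();
    w.phi = acc.data();
    for (int b = 0; b < n_ref; ++b) {
      for (int j = 0; j < n_feat; ++j) rrow[j] = R(b, j);
      w.r = rrow.data();
      for (int t = 0; t < tree_root.size(); ++t) w.walk(tree_root[t]);
    }
    for (int j = 0; j < n_feat; ++j) phi(i, j) = acc[j] / n_ref;
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return phi;
}
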