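// CART regression forest and exact interventional Shapley attribution for
// its trees. Kept deliberately small: bootstrap bagging, variance-reduction
// splits over mtry sampled features, depth/min-node stopping. All randomness
// flows through R's RNG so set.seed() on the R side makes fits reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  // node arrays; feature == -1 marks a leaf
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> value;
};

int grow_node(Tree& tr, const NumericMatrix& X, const NumericVector& y,
              std::vector<int>& idx, int lo, int hi, int depth,
              int max_depth, int min_node, int mtry) {
  const int node = (int)tr.feature.size();
  tr.feature.push_back(-1);
  tr.threshold.push_back(0.0);
  tr.left.push_back(-1);
  tr.right.push_back(-1);

  const int n = hi - lo;
  double sum = 0.0;
  for (int k = lo; k < hi; ++k) sum += y[idx[k]];
  const double mean = sum / n;
  tr.value.push_back(mean);

  if (depth >= max_depth || n < 2 * min_node) return node;

  double sse = 0.0;
  for (int k = lo; k < hi; ++k) {
    const double d = y[idx[k]] - mean;
    sse += d * d;
  }
  if (sse <= 1e-12) return node;

  const int p = X.ncol();
  // sample mtry distinct features via partial Fisher-Yates on R's RNG
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + (int)(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, double>> xy(n);
  for (int j = 0; j < m; ++j) {
    const int f = feats[j];
    for (int k = 0; k < n; ++k)
      xy[k] = std::make_pair(X(idx[lo + k], f), y[idx[lo + k]]);
    std::sort(xy.begin(), xy.end());
    double lsum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += xy[k].second;
      if (xy[k].first >= xy[k + 1].first) continue;  // no split between ties
      const int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      const double rsum = sum - lsum;
      const double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = f;
        best_thr = 0.5 * (xy[k].first + xy[k + 1].first);
      }
    }
  }
  if (best_feat < 0) return node;

  // partition idx[lo, hi) in place
  int i = lo, jj = hi - 1;
  while (i <= jj) {
    if (X(idx[i], best_feat) <= best_thr) ++i;
    else std::swap(idx[i], idx[jj--]);
  }
  if (i == lo || i == hi) return node;  // numeric degeneracy

  tr.feature[node] = best_feat;
  tr.threshold[node] = best_thr;
  tr.left[node] = grow_node(tr, X, y, idx, lo, i, depth + 1, max_depth, min_node, mtry);
  tr.right[node] = grow_node(tr, X, y, idx, i, hi, depth + 1, max_depth, min_node, mtry);
  return node;
}

double predict_tree(const IntegerVector& feature, const NumericVector& threshold,
                    const IntegerVector& left, const IntegerVector& right,
                    const NumericVector& value, const NumericMatrix& X, int row) {
  int node = 0;
  while (feature[node] >= 0)
    node = (X(row, feature[node]) <= threshold[node]) ? left[node] : right[node];
  return value[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                int max_depth, int min_node) {
  const int n = X.nrow();
  List trees(n_trees);
  GetRNGstate();
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    for (int k = 0; k < n; ++k) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[k] = r;
    }
    Tree tr;
    grow_node(tr, X, y, idx, 0, n, 0, max_depth, min_node, mtry);
    trees[t] = List::create(
        _["feature"] = wrap(tr.feature), _["threshold"] = wrap(tr.threshold),
        _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
        _["value"] = wrap(tr.value));
  }
  PutRNGstate();
  return trees;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i)
      out[i] += predict_tree(feature, threshold, left, right, value, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}

namespace {

// A leaf with its path constraints collapsed to one interval per distinct
// feature: the leaf is reached by a point z iff lo < z_f <= hi for every
// constrained feature f.
struct Leaf {
  double value;
  std::vector<int> feats;
  std::vector<double> lo, hi;
};

void collect_leaves(const IntegerVector& feature, const NumericVector& threshold,
                    const IntegerVector& left, const IntegerVector& right,
                    const NumericVector& value, int node,
                    std::vector<int>& pf, std::vector<double>& plo,
                    std::vector<double>& phi, std::vector<Leaf>& out) {
  if (feature[node] < 0) {
    Leaf lf;
    lf.value = value[node];
    // collapse repeated features on the path
    for (size_t k = 0; k < pf.size(); ++k) {
      bool seen = false;
      for (size_t q = 0; q < lf.feats.size(); ++q)
        if (lf.feats[q] == pf[k]) {
          lf.lo[q] = std::max(lf.lo[q], plo[k]);
          lf.hi[q] = std::min(lf.hi[q], phi[k]);
          seen = true;
          break;
        }
      if (!seen) {
        lf.feats.push_back(pf[k]);
        lf.lo.push_back(plo[k]);
        lf.hi.push_back(phi[k]);
      }
    }
    out.push_back(lf);
    return;
  }
  const double thr = threshold[node];
  const double inf = std::numeric_limits<double>::infinity();
  pf.push_back(feature[node]); plo.push_back(-inf); phi.push_back(thr);
  collect_leaves(feature, threshold, left, right, value, left[node], pf, plo, phi, out);
  plo.back() = thr; phi.back() = inf;
  collect_leaves(feature, threshold, left, right, value, right[node], pf, plo, phi, out);
  pf.pop_back(); plo.pop_back(); phi.pop_back();
}

inline bool passes(double v, double lo, double hi) { return v > lo && v <= hi; }

}  // namespace

// Exact interventional Shapley values for a tree ensemble, averaged over a
// background matrix. For each (leaf, instance x, background row b) the leaf's
// indicator game over the hybrid points [x on S, b off S] is an AND-game whose
// Shapley values have the closed form
//   i in S_x: +v * (a-1)! c! / (a+c)!,   j in S_b: -v * a! (c-1)! / (a+c)!
// with a = |S_x| (path features only x passes), c = |S_b| (only b passes);
// a leaf some path feature of which neither x nor b passes contributes 0.
// [[Rcpp::export(name = ".tree_shap_cpp")]]
List tree_shap_cpp(List trees, NumericMatrix X, NumericMatrix BG) {
  const int M = X.nrow(), B = BG.nrow(), P = X.ncol(), T = trees.size();
  NumericMatrix phi(M, P);
  std::vector<double> fact(64);
  fact[0] = 1.0;
  for (int k = 1; k < 64; ++k) fact[k] = fact[k - 1] * k;

  double base = 0.0;
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector value = tr["value"];

    std::vector<Leaf> leaves;
    std::vector<int> pf;
    std::vector<double> plo, phv;
    collect_leaves(feature, threshold, left, right, value, 0, pf, plo, phv, leaves);

    for (int b = 0; b < B; ++b)
      base += predict_tree(feature, threshold, left, right, value, BG, b);

    const size_t L = leaves.size();
    // pass bits for background rows, per leaf (reused across instances)
    std::vector<std::vector<unsigned>> passb(L, std::vector<unsigned>(B, 0u));
    for (size_t l = 0; l < L; ++l) {
      const Leaf& lf = leaves[l];
      const size_t K = lf.feats.size();
      for (int b = 0; b < B; ++b) {
        unsigned bits = 0u;
        for (size_t k = 0; k < K; ++k)
          if (passes(BG(b, lf.feats[k]), lf.lo[k], lf.hi[k])) bits |= (1u << k);
        passb[l][b] = bits;
      }
    }

    for (int i = 0; i < M; ++i) {
      for (size_t l = 0; l < L; ++l) {
        const Leaf& lf = leaves[l];
        const size_t K = lf.feats.size();
        if (K == 0) continue;  // constant tree: no attribution
        unsigned px = 0u;
        for (size_t k = 0; k < K; ++k)
          if (passes(X(i, lf.feats[k]), lf.lo[k], lf.hi[k])) px |= (1u << k);
        const unsigned full = (K >= 32) ? 0xffffffffu : ((1u << K) - 1u);
        for (int b = 0; b < B; ++b) {
          const unsigned pb = passb[l][b];
          if ((px | pb) != full) continue;  // some feature blocked both ways
          const unsigned only_x = px & ~pb, only_b = pb & ~px;
          const int a = __builtin_popcount(only_x), c = __builtin_popcount(only_b);
          if (a == 0 && c == 0) continue;
          const double v = lf.value;
          if (a > 0) {
            const double w = v * fact[a - 1] * fact[c] / fact[a + c];
            for (size_t k = 0; k < K; ++k)
              if (only_x & (1u << k)) phi(i, lf.feats[k]) += w;
          }
          if (c > 0) {
            const double w = v * fact[a] * fact[c - 1] / fact[a + c];
            for (size_t k = 0; k < K; ++k)
              if (only_b & (1u << k)) phi(i, lf.feats[k]) -= w;
          }
        }
      }
    }
  }
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < P; ++j) phi(i, j) /= (double)(B * T);
  base /= (double)(B * T);
  return List::create(_["phi"] = phi, _["base_value"] = base);
}
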