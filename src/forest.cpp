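#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Portable deterministic RNG (splitmix64): forest results must be
// bitwise-reproducible for a given seed across platforms, so we do not
// depend on R's RNG stream or std::uniform_int_distribution.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  int randint(int k) { return (int)(next() % (uint64_t)k); }
};

// impurity of a node: sum over labels of (cnt - cnt^2/n)  [variance/PCT form]
// gini form is the same scaled by 2/m; labels are binary so sum(y^2)=sum(y).
static inline double node_impurity(const std::vector<double>& cnt, double n,
                                   int criterion, int m) {
  double imp = 0.0;
  for (int l = 0; l < m; ++l) imp += cnt[l] - cnt[l] * cnt[l] / n;
  if (criterion == 1) imp *= 2.0 / (double)m;
  return imp;
}

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericMatrix& Y;
  int n, f, m;
  int mtry, min_node, max_depth, criterion;
  SplitMix rng;

  std::vector<int> feat, left, right;
  std::vector<double> thr;
  std::vector<double> values; // node-major, length n_nodes*m (mean label vector)

  TreeBuilder(const NumericMatrix& X_, const NumericMatrix& Y_, int mtry_,
              int min_node_, int max_depth_, int criterion_, uint64_t seed)
      : X(X_), Y(Y_), n(X_.nrow()), f(X_.ncol()), m(Y_.ncol()), mtry(mtry_),
        min_node(min_node_), max_depth(max_depth_), criterion(criterion_),
        rng(seed) {}

  int new_node(const std::vector<double>& cnt, double nn) {
    int id = (int)feat.size();
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    for (int l = 0; l < m; ++l) values.push_back(cnt[l] / nn);
    return id;
  }

  // find best split on one feature; returns gain (-1 if no valid split)
  double best_split_feature(int p, const std::vector<int>& idx,
                            const std::vector<double>& cnt, double parent_imp,
                            double& best_thr_out) {
    size_t nn = idx.size();
    std::vector<std::pair<double, int> > v(nn);
    for (size_t i = 0; i < nn; ++i) v[i] = std::make_pair(X(idx[i], p), idx[i]);
    std::sort(v.begin(), v.end());
    if (v.front().first == v.back().first) return -1.0;

    std::vector<double> lcnt(m, 0.0);
    double best_gain = -1.0;
    double nL = 0.0;
    for (size_t i = 0; i + 1 < nn; ++i) {
      int r = v[i].second;
      for (int l = 0; l < m; ++l) lcnt[l] += Y(r, l);
      nL += 1.0;
      if (v[i].first == v[i + 1].first) continue; // not a boundary
      if (nL < min_node || (nn - nL) < min_node) continue;
      double impL = 0.0, impR = 0.0;
      double nR = (double)nn - nL;
      for (int l = 0; l < m; ++l) {
        impL += lcnt[l] - lcnt[l] * lcnt[l] / nL;
        double rc = cnt[l] - lcnt[l];
        impR += rc - rc * rc / nR;
      }
      if (criterion == 1) { impL *= 2.0 / m; impR *= 2.0 / m; }
      double gain = parent_imp - impL - impR;
      if (gain > best_gain + 1e-15) { // first (lowest) threshold wins ties
        best_gain = gain;
        best_thr_out = 0.5 * (v[i].first + v[i + 1].first);
      }
    }
    return best_gain;
  }

  int build(std::vector<int>& idx, int depth) {
    double nn = (double)idx.size();
    std::vector<double> cnt(m, 0.0);
    for (size_t i = 0; i < idx.size(); ++i)
      for (int l = 0; l < m; ++l) cnt[l] += Y(idx[i], l);
    int id = new_node(cnt, nn);

    double parent_imp = node_impurity(cnt, nn, criterion, m);
    bool pure = parent_imp <= 1e-12;
    if (idx.size() < 2 || (size_t)idx.size() < (size_t)(2 * min_node) ||
        pure || (max_depth > 0 && depth >= max_depth))
      return id;

    // sample mtry distinct features (partial Fisher-Yates), search ascending
    std::vector<int> cand(f);
    for (int p = 0; p < f; ++p) cand[p] = p;
    int k = std::min(mtry, f);
    for (int i = 0; i < k; ++i) {
      int j = i + rng.randint(f - i);
      std::swap(cand[i], cand[j]);
    }
    cand.resize(k);
    std::sort(cand.begin(), cand.end()); // lowest feature index breaks ties

    int best_p = -1;
    double best_gain = 1e-12, best_thr = 0.0;
    for (int ci = 0; ci < k; ++ci) {
      double t = 0.0;
      double g = best_split_feature(cand[ci], idx, cnt, parent_imp, t);
      if (g > best_gain) { best_gain = g; best_p = cand[ci]; best_thr = t; }
    }

    // impure node with no impurity-reducing split (e.g. XOR structure):
    // force the first available partition so deeper splits can resolve it
    if (best_p < 0) {
      for (int ci = 0; ci < k && best_p < 0; ++ci) {
        int p = cand[ci];
        double lo = X(idx[0], p), hi = lo;
        for (size_t i = 1; i < idx.size(); ++i) {
          double v = X(idx[i], p);
          if (v < lo) lo = v;
          if (v > hi) hi = v;
        }
        if (hi > lo) {
          double second = hi;
          for (size_t i = 0; i < idx.size(); ++i) {
            double v = X(idx[i], p);
            if (v > lo && v < second) second = v;
          }
          best_p = p;
          best_thr = 0.5 * (lo + second);
        }
      }
      if (best_p < 0) return id; // all candidate features constant
    }

    std::vector<int> lidx, ridx;
    for (size_t i = 0; i < idx.size(); ++i) {
      if (X(idx[i], best_p) <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) return id;

    feat[id] = best_p;
    thr[id] = best_thr;
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    left[id] = l;
    right[id] = r;
    return id;
  }
};

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, NumericMatrix Y, int n_trees, int mtry,
                     int criterion, int min_node, int max_depth, bool bootstrap,
                     double seed) {
  int n = X.nrow();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    uint64_t tree_seed =
        (uint64_t)seed * 0x100000001ULL + (uint64_t)(t + 1) * 0x9e3779b9ULL;
    TreeBuilder tb(X, Y, mtry, min_node, max_depth, criterion, tree_seed);
    std::vector<int> idx(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = tb.rng.randint(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }
    tb.build(idx, 0);
    int nn = (int)tb.feat.size();
    NumericMatrix vals(nn, Y.ncol());
    for (int i = 0; i < nn; ++i)
      for (int l = 0; l < Y.ncol(); ++l) vals(i, l) = tb.values[i * Y.ncol() + l];
    trees[t] = List::create(_["feature"] = wrap(tb.feat),
                            _["threshold"] = wrap(tb.thr),
                            _["left"] = wrap(tb.left),
                            _["right"] = wrap(tb.right),
                            _["values"] = vals);
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix predict_forest_cpp(List trees, NumericMatrix X, int m) {
  int n = X.nrow();
  int T = trees.size();
  NumericMatrix out(n, m);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feature"];
    NumericVector thr = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericMatrix vals = tr["values"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      for (int l = 0; l < m; ++l) out(i, l) += vals(node, l);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < m; ++l) out(i, l) /= (double)T;
  return out;
}
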