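#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Minimal CART/bagging random forest for binary classification.
// Trees are returned as plain numeric matrices (one row per node) so that
// fitted ensembles serialize with base R and contain no external pointers.
// Node columns: 0 feat (0-based, -1 = leaf), 1 threshold, 2 left, 3 right
// (0-based row indices, -1 = none), 4 prob (positive fraction), 5 n.

namespace {

// xorshift64* generator: identical streams on every platform/compiler,
// unlike std::uniform_int_distribution.
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Node {
  int feat = -1;
  double thr = 0.0;
  int left = -1, right = -1;
  double prob = 0.0;
  int n = 0;
};

double gini_pair(double pos, double n) {
  if (n <= 0) return 0.0;
  double p = pos / n;
  return 2.0 * p * (1.0 - p);
}

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  RNG& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, int max_depth_, RNG& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), max_depth(max_depth_),
        rng(rng_) {}

  int build(std::vector<int>& idx, int depth) {
    int me = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    int n = static_cast<int>(idx.size());
    int pos = 0;
    for (int i : idx) pos += y[i];
    nodes[me].n = n;
    nodes[me].prob = n > 0 ? static_cast<double>(pos) / n : 0.0;
    bool pure = (pos == 0 || pos == n);
    if (pure || n < 2 * min_node || (max_depth > 0 && depth >= max_depth))
      return me;

    int p = X.ncol();
    // sample mtry distinct feature indices (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j)
      std::swap(feats[j], feats[j + rng.below(p - j)]);

    double best_imp = -1.0;
    int best_f = -1;
    double best_thr = 0.0;
    double parent = gini_pair(pos, n) * n;
    std::vector<std::pair<double, int> > vals(n);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int t = 0; t < n; ++t) vals[t] = std::make_pair(X(idx[t], f), y[idx[t]]);
      std::sort(vals.begin(), vals.end());
      double lpos = 0.0;
      for (int t = 0; t < n - 1; ++t) {
        lpos += vals[t].second;
        if (vals[t].first == vals[t + 1].first) continue;
        double ln = t + 1.0, rn = n - ln, rpos = pos - lpos;
        double imp = parent - gini_pair(lpos, ln) * ln - gini_pair(rpos, rn) * rn;
        if (imp > best_imp + 1e-12) {
          best_imp = imp;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0 || best_imp <= 1e-12) return me;

    std::vector<int> lidx, ridx;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? lidx : ridx).push_back(i);
    if (lidx.empty() || ridx.empty()) return me;
    nodes[me].feat = best_f;
    nodes[me].thr = best_thr;
    nodes[me].left = build(lidx, depth + 1);
    nodes[me].right = build(ridx, depth + 1);
    return me;
  }
};

double predict_tree(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int f = static_cast<int>(tree(node, 0));
    node = X(row, f) <= tree(node, 1) ? static_cast<int>(tree(node, 2))
                                      : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

}  // namespace

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                     int min_node, int max_depth, double seed) {
  int n = X.nrow();
  if (n != y.size()) stop("X and y sizes differ");
  RNG rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rng.below(n);
    TreeBuilder tb(X, y, mtry, min_node, max_depth, rng);
    tb.build(boot, 0);
    NumericMatrix m(static_cast<int>(tb.nodes.size()), 6);
    for (size_t k = 0; k < tb.nodes.size(); ++k) {
      const Node& nd = tb.nodes[k];
      m(k, 0) = nd.feat; m(k, 1) = nd.thr; m(k, 2) = nd.left;
      m(k, 3) = nd.right; m(k, 4) = nd.prob; m(k, 5) = nd.n;
    }
    forest[t] = m;
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  int n = X.nrow(), ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  if (ntree > 0) out = out / ntree;
  return out;
}
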