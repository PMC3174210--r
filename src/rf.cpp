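// Compact Breiman-style random forest for binary classification.
// Per tree: bootstrap of size n, CART with Gini splits, mtry candidate
// features per node sampled without replacement, grown to purity
// (min_node = 1), no pruning. Prediction is the majority vote over trees;
// a tied vote goes to class 0 (the first factor level). All randomness
// comes from std::mt19937 seeded deterministically from (seed, tree index),
// independent of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feat;      // split feature, -1 for leaf
  std::vector<double> thr;    // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<int> pred;      // leaf class, -1 for internal nodes
};

int make_leaf(Tree &t, int c0, int c1) {
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(c1 > c0 ? 1 : 0);  // tie -> class 0
  return static_cast<int>(t.feat.size()) - 1;
}

int grow(Tree &t, const NumericMatrix &X, const IntegerVector &y,
         std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
         std::mt19937 &rng) {
  const int n = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
  const int c0 = n - c1;
  if (c0 == 0 || c1 == 0 || n < 2 * min_node || n < 2)
    return make_leaf(t, c0, c1);

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  const int m_try = std::min(mtry, p);
  for (int j = 0; j < m_try; ++j) {
    std::uniform_int_distribution<int> d(j, p - 1);
    std::swap(feats[j], feats[d(rng)]);
  }

  double best_score = -1.0, best_thr = 0.0;
  int best_f = -1;
  std::vector<std::pair<double, int> > vals(n);
  for (int m = 0; m < m_try; ++m) {
    const int f = feats[m];
    for (int i = 0; i < n; ++i) {
      const int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (!(vals[i + 1].first > vals[i].first)) continue;
      const int nl = i + 1, nr = n - nl;
      const int l0 = nl - l1, r1 = c1 - l1, r0 = nr - r1;
      // maximizing sum_k n_side * sum_c p_c^2 is equivalent to minimizing
      // the weighted Gini impurity of the two children
      const double score =
          (static_cast<double>(l0) * l0 + static_cast<double>(l1) * l1) / nl +
          (static_cast<double>(r0) * r0 + static_cast<double>(r1) * r1) / nr;
      if (score > best_score) {
        best_score = score;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return make_leaf(t, c0, c1);  // all candidates constant

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return make_leaf(t, c0, c1);

  const int node = static_cast<int>(t.feat.size());
  t.feat.push_back(best_f);
  t.thr.push_back(best_thr);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.pred.push_back(-1);
  const int L = grow(t, X, y, idx, lo, mid, mtry, min_node, rng);
  const int R = grow(t, X, y, idx, mid, hi, mtry, min_node, rng);
  t.left[node] = L;
  t.right[node] = R;
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node, int seed) {
  const int n = X.nrow();
  if (n_trees < 1) stop("n_trees must be >= 1");
  if (mtry < 1 || mtry > X.ncol()) stop("mtry must be in [1, ncol(X)]");
  List forest(n_trees);
  for (int tr = 0; tr < n_trees; ++tr) {
    std::seed_seq seq{static_cast<std::uint32_t>(seed),
                      static_cast<std::uint32_t>(tr)};
    std::mt19937 rng(seq);
    std::uniform_int_distribution<int> boot(0, n - 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    Tree t;
    const int root = grow(t, X, y, idx, 0, n, mtry, min_node, rng);
    forest[tr] = List::create(
        _["feat"] = wrap(t.feat), _["thr"] = wrap(t.thr),
        _["left"] = wrap(t.left), _["right"] = wrap(t.right),
        _["pred"] = wrap(t.pred), _["root"] = root);
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_votes_cpp")]]
IntegerVector rf_votes_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  IntegerVector votes1(n);  // votes for class 1 per row
  for (int tr = 0; tr < T; ++tr) {
    const List tree = forest[tr];
    const IntegerVector feat = tree["feat"], left = tree["left"],
                        right = tree["right"], pred = tree["pred"];
    const NumericVector thr = tree["thr"];
    const int root = tree["root"];
    for (int i = 0; i < n; ++i) {
      int node = root;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      votes1[i] += pred[node];
    }
  }
  return votes1;
}
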