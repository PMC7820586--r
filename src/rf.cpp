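// Bagged CART classification forest (Breiman-style):
// bootstrap resampling per tree, random feature subsampling at each split,
// Gini impurity, trees grown to purity. Uses R's RNG so results are fully
// reproducible under set.seed().
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TreeNodes {
  // node arrays; leaf iff feature == -1
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> leaf_value; // mean label at leaf
};

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  TreeNodes tree;
  std::vector<double> imp; // Gini importance accumulator per feature

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_, int min_node_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), imp(X_.ncol(), 0.0) {}

  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    int pos = 0;
    for (int t = lo; t < hi; ++t) pos += y[idx[t]];
    int id = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.leaf_value.push_back((double)pos / n);
    if (pos == 0 || pos == n || n < 2 * min_node || n < 2) return id;

    double parent_gini = 2.0 * pos * (n - pos) / ((double)n * n);
    int p = X.ncol();
    // sample mtry features without replacement (partial Fisher-Yates, R RNG)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + (int)(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int t = 0; t < n; ++t)
        vals[t] = {X(idx[lo + t], f), y[idx[lo + t]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int lpos = 0;
      for (int t = 0; t < n - 1; ++t) {
        lpos += vals[t].second;
        if (vals[t].first == vals[t + 1].first) continue;
        int ln = t + 1, rn = n - ln;
        int rpos = pos - lpos;
        double gl = 2.0 * lpos * (ln - lpos) / ((double)ln * ln);
        double gr = 2.0 * rpos * (rn - rpos) / ((double)rn * rn);
        double gain = parent_gini - ((double)ln / n) * gl - ((double)rn / n) * gr;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0) return id; // no informative split among sampled features

    imp[best_f] += best_gain * n;
    // partition idx[lo, hi) in place
    int mid = lo;
    for (int t = lo; t < hi; ++t)
      if (X(idx[t], best_f) <= best_thr) std::swap(idx[t], idx[mid++]);
    tree.feature[id] = best_f;
    tree.threshold[id] = best_thr;
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    tree.left[id] = l;
    tree.right[id] = r;
    return id;
  }
};

double tree_predict_row(const NumericMatrix& tr, const NumericMatrix& X, int row) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    int f = (int)tr(node, 0);
    node = (X(row, f) <= tr(node, 1)) ? (int)tr(node, 2) : (int)tr(node, 3);
  }
  return tr(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_train_cpp")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                  int min_node) {
  int n = X.nrow(), p = X.ncol();
  RNGScope scope;
  List forest(n_trees);
  std::vector<double> importance(p, 0.0);
  std::vector<double> oob_vote(n, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<char> inbag(n);
  for (int b = 0; b < n_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[t] = k;
      inbag[k] = 1;
    }
    Builder bld(X, y, mtry, min_node);
    bld.build(idx, 0, n);
    int nn = (int)bld.tree.feature.size();
    NumericMatrix tm(nn, 5);
    for (int t = 0; t < nn; ++t) {
      tm(t, 0) = bld.tree.feature[t];
      tm(t, 1) = bld.tree.threshold[t];
      tm(t, 2) = bld.tree.left[t];
      tm(t, 3) = bld.tree.right[t];
      tm(t, 4) = bld.tree.leaf_value[t];
    }
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) {
        oob_vote[i] += (tree_predict_row(tm, X, i) >= 0.5) ? 1.0 : 0.0;
        ++oob_count[i];
      }
    forest[b] = tm;
    for (int j = 0; j < p; ++j) importance[j] += bld.imp[j];
  }
  NumericVector oob(n);
  for (int i = 0; i < n; ++i)
    oob[i] = oob_count[i] > 0 ? oob_vote[i] / oob_count[i] : NA_REAL;
  return List::create(_["forest"] = forest,
                      _["importance"] = NumericVector(importance.begin(), importance.end()),
                      _["oob_prob"] = oob);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), B = forest.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) {
    NumericMatrix tr = forest[b];
    for (int i = 0; i < n; ++i)
      out[i] += (tree_predict_row(tr, X, i) >= 0.5) ? 1.0 : 0.0;
  }
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}
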