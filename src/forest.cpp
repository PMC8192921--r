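#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Bagged CART forest: gini impurity, per-node random feature subsampling
// (mtry), bootstrap resampling, trees grown to purity (min_node = 1).
// All randomness is drawn from R's RNG so set.seed() on the R side fully
// determines training.

namespace {

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> pred;      // class-1 fraction at leaf
};

int sample_int(int n) {  // uniform on 0..n-1 via R RNG
  int k = static_cast<int>(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

void grow(TreeNodes &tree, const NumericMatrix &x, const IntegerVector &y,
          std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
          std::vector<int> &feat_pool) {
  int node = static_cast<int>(tree.feature.size());
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);

  int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  double p1 = static_cast<double>(n1) / n;
  tree.pred.push_back(p1);
  if (n < min_node || n1 == 0 || n1 == n) return;

  int p = static_cast<int>(feat_pool.size());
  double best_score = R_PosInf;
  int best_f = -1;
  double best_thr = 0.0;

  // partial Fisher-Yates: first mtry entries of feat_pool become candidates
  for (int j = 0; j < mtry && j < p; ++j) {
    int k = j + sample_int(p - j);
    std::swap(feat_pool[j], feat_pool[k]);
  }

  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int j = 0; j < mtry && j < p; ++j) {
    int f = feat_pool[j];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return x(a, f) < x(b, f);
    });
    int left1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      left1 += y[ord[i]];
      if (x(ord[i + 1], f) <= x(ord[i], f)) continue;  // no gap between values
      int nl = i + 1, nr = n - nl;
      double pl = static_cast<double>(left1) / nl;
      double pr = static_cast<double>(n1 - left1) / nr;
      double score = nl * pl * (1.0 - pl) + nr * pr * (1.0 - pr);
      if (score < best_score) {
        best_score = score;
        best_f = f;
        best_thr = (x(ord[i], f) + x(ord[i + 1], f)) / 2.0;
      }
    }
  }
  if (best_f < 0) return;  // all candidate features constant within node

  int mid = lo;  // partition idx[lo..hi) by the chosen split
  for (int i = lo; i < hi; ++i) {
    if (x(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  }
  if (mid == lo || mid == hi) return;  // degenerate (should not happen)

  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  tree.left[node] = static_cast<int>(tree.feature.size());
  grow(tree, x, y, idx, lo, mid, mtry, min_node, feat_pool);
  tree.right[node] = static_cast<int>(tree.feature.size());
  grow(tree, x, y, idx, mid, hi, mtry, min_node, feat_pool);
}

}  // namespace

// [[Rcpp::export]]
List rf_train_cpp(NumericMatrix x, IntegerVector y, int ntree, int mtry,
                  int min_node) {
  int n = x.nrow(), p = x.ncol();
  List forest(ntree);
  RNGScope scope;
  std::vector<int> feat_pool(p);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = sample_int(n);  // bootstrap
    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    TreeNodes tree;
    grow(tree, x, y, idx, 0, n, mtry, std::max(2, min_node), feat_pool);
    int m = static_cast<int>(tree.feature.size());
    NumericMatrix nodes(m, 5);
    for (int i = 0; i < m; ++i) {
      nodes(i, 0) = tree.feature[i];
      nodes(i, 1) = tree.threshold[i];
      nodes(i, 2) = tree.left[i];
      nodes(i, 3) = tree.right[i];
      nodes(i, 4) = tree.pred[i];
    }
    forest[t] = nodes;
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix x) {
  int n = x.nrow(), ntree = forest.size();
  NumericVector score(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix nodes = forest[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (nodes(node, 0) >= 0) {
        int f = static_cast<int>(nodes(node, 0));
        node = (x(i, f) <= nodes(node, 1)) ? static_cast<int>(nodes(node, 2))
                                           : static_cast<int>(nodes(node, 3));
      }
      if (nodes(node, 4) >= 0.5) score[i] += 1.0;  // hard vote
    }
  }
  return score / static_cast<double>(ntree);
}
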