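// Compact random-forest classifier used by the LOOCV / transfer
// evaluation stages. Bagged CART trees with Gini splits and per-node
// random feature subsets; probability = fraction of trees voting for the
// positive class (leaf-majority vote, ties split 0.5). Uses R's RNG so
// results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;      // -1 marks a leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double pos_frac = 0.0; // positive fraction in the leaf
};

struct Tree {
  std::vector<Node> nodes;
};

int rand_int(int n) {  // uniform on 0..n-1 via R RNG
  int v = static_cast<int>(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// grow a node over sample indices idx; returns node id
int grow(std::vector<Node>& nodes, const NumericMatrix& X,
         const IntegerVector& y, std::vector<int>& idx, int lo, int hi,
         int mtry, int min_node, int depth) {
  int node_id = static_cast<int>(nodes.size());
  nodes.push_back(Node());
  int n = hi - lo;
  int npos = 0;
  for (int t = lo; t < hi; ++t) npos += y[idx[t]];
  double frac = n > 0 ? static_cast<double>(npos) / n : 0.5;
  nodes[node_id].pos_frac = frac;
  if (n < 2 * min_node || npos == 0 || npos == n || depth > 64)
    return node_id;

  const int p = X.ncol();
  // sample mtry distinct features (partial Fisher-Yates over a scratch list)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int ntry = std::min(mtry, p);

  double best_gain = 0.0;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int> > vals;
  vals.reserve(n);
  double parent_gini = 2.0 * frac * (1.0 - frac);

  for (int f = 0; f < ntry; ++f) {
    int pick = f + rand_int(p - f);
    std::swap(feats[f], feats[pick]);
    int j = feats[f];
    vals.clear();
    for (int t = lo; t < hi; ++t)
      vals.push_back(std::make_pair(X(idx[t], j), y[idx[t]]));
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    int left_n = 0, left_pos = 0;
    for (int t = 0; t < n - 1; ++t) {
      left_n += 1;
      left_pos += vals[t].second;
      if (vals[t].first == vals[t + 1].first) continue;
      int right_n = n - left_n;
      int right_pos = npos - left_pos;
      double pl = static_cast<double>(left_pos) / left_n;
      double pr = static_cast<double>(right_pos) / right_n;
      double gini = (left_n * 2.0 * pl * (1.0 - pl) +
                     right_n * 2.0 * pr * (1.0 - pr)) / n;
      double gain = parent_gini - gini;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
      }
    }
  }
  if (best_feat < 0) return node_id;

  // partition idx[lo:hi) in place
  int mid = lo;
  for (int t = lo; t < hi; ++t)
    if (X(idx[t], best_feat) <= best_thr) std::swap(idx[t], idx[mid++]);
  if (mid == lo || mid == hi) return node_id;

  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  int left = grow(nodes, X, y, idx, lo, mid, mtry, min_node, depth + 1);
  int right = grow(nodes, X, y, idx, mid, hi, mtry, min_node, depth + 1);
  nodes[node_id].feature = best_feat;  // vector may have reallocated
  nodes[node_id].threshold = best_thr;
  nodes[node_id].left = left;
  nodes[node_id].right = right;
  return node_id;
}

double predict_tree(const std::vector<Node>& nodes, const NumericMatrix& X,
                    int row) {
  int cur = 0;
  while (nodes[cur].feature >= 0) {
    cur = (X(row, nodes[cur].feature) <= nodes[cur].threshold)
            ? nodes[cur].left : nodes[cur].right;
  }
  return nodes[cur].pos_frac;
}

}  // namespace

// [[Rcpp::export]]
NumericVector rf_train_predict(NumericMatrix Xtrain, IntegerVector ytrain,
                               NumericMatrix Xtest, int ntree, int mtry,
                               int min_node) {
  if (Xtrain.nrow() != ytrain.size())
    stop("training rows and labels disagree");
  if (Xtrain.ncol() != Xtest.ncol())
    stop("train/test feature counts disagree");
  const int n = Xtrain.nrow();
  const int nte = Xtest.nrow();
  RNGScope scope;
  NumericVector votes(nte);
  std::vector<int> idx(n);
  for (int b = 0; b < ntree; ++b) {
    for (int t = 0; t < n; ++t) idx[t] = rand_int(n);  // bootstrap
    std::vector<Node> nodes;
    nodes.reserve(2 * n);
    grow(nodes, Xtrain, ytrain, idx, 0, n, mtry, min_node, 0);
    for (int r = 0; r < nte; ++r) {
      double frac = predict_tree(nodes, Xtest, r);
      votes[r] += (frac > 0.5) ? 1.0 : (frac == 0.5 ? 0.5 : 0.0);
    }
  }
  for (int r = 0; r < nte; ++r) votes[r] /= ntree;
  return votes;
}
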