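#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Weighted CART with best-first node expansion and a hard cap on the total
// number of splits (the semantics of a "maximum number of splits"
// hyper-parameter). Supports Gini impurity for classification (with
// observation weights, as required by boosting) and weighted SSE for
// regression. Trees are returned as flat parallel arrays; prediction is a
// simple traversal. Ties in sorting are broken by row index so the grown
// tree is fully deterministic.

struct SplitInfo {
  double gain;
  int node;          // index into node arrays
  int feature;
  double threshold;
  std::vector<int> left_rows, right_rows;
  int uid;           // insertion id; older candidate wins ties -> determinism
  bool operator<(const SplitInfo& o) const {
    if (gain != o.gain) return gain < o.gain;
    return uid < o.uid; // priority_queue: top() is max
  }
};

struct TreeBuild {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;      // value = weighted mean (regression)
  std::vector<std::vector<double>> dist;     // class distribution (classification)
};

// impurity of a node given aggregated stats
static inline double node_impurity_cls(const std::vector<double>& cw, double W) {
  if (W <= 0) return 0.0;
  double s = 0.0;
  for (double c : cw) s += (c / W) * (c / W);
  return W * (1.0 - s);
}

// Find the best split of rows; returns gain (<=0 if none).
static bool best_split(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& w, const std::vector<int>& rows,
                       bool classify, int K, int min_leaf,
                       int& bf, double& bt, double& bgain) {
  int n = rows.size(), p = X.ncol();
  if (n < 2 * min_leaf) return false;
  // parent impurity
  double W = 0.0, Sy = 0.0, Syy = 0.0;
  std::vector<double> cw(classify ? K : 0, 0.0);
  for (int r : rows) {
    W += w[r];
    if (classify) cw[(int)y[r]] += w[r];
    else { Sy += w[r] * y[r]; Syy += w[r] * y[r] * y[r]; }
  }
  double imp_parent = classify ? node_impurity_cls(cw, W)
                               : (Syy - Sy * Sy / std::max(W, 1e-300));
  bgain = 1e-12; bf = -1; bt = 0.0;
  std::vector<std::pair<double,int>> vals(n);
  for (int j = 0; j < p; j++) {
    for (int i = 0; i < n; i++) vals[i] = std::make_pair(X(rows[i], j), rows[i]);
    std::stable_sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double Wl = 0.0, Syl = 0.0;
    std::vector<double> cwl(classify ? K : 0, 0.0);
    for (int i = 0; i < n - 1; i++) {
      int r = vals[i].second;
      Wl += w[r];
      if (classify) cwl[(int)y[r]] += w[r];
      else Syl += w[r] * y[r];
      if (vals[i].first == vals[i + 1].first) continue;
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      double imp_children;
      if (classify) {
        double Wr = W - Wl;
        std::vector<double> cwr(K);
        for (int k = 0; k < K; k++) cwr[k] = cw[k] - cwl[k];
        imp_children = node_impurity_cls(cwl, Wl) + node_impurity_cls(cwr, Wr);
      } else {
        double Wr = W - Wl, Syr = Sy - Syl;
        double sse_l = Wl > 0 ? -Syl * Syl / Wl : 0.0;
        double sse_r = Wr > 0 ? -Syr * Syr / Wr : 0.0;
        // constant Syy cancels in the gain; add parent's -Sy^2/W via imp_parent
        imp_children = Syy + sse_l + sse_r;
      }
      double gain = imp_parent - imp_children;
      if (gain > bgain) {
        bgain = gain; bf = j;
        bt = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  return bf >= 0;
}

static int add_leaf(TreeBuild& T, const NumericVector& y, const NumericVector& w,
                    const std::vector<int>& rows, bool classify, int K) {
  T.feature.push_back(-1); T.threshold.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);
  double W = 0.0, Sy = 0.0;
  std::vector<double> cw(classify ? K : 0, 0.0);
  for (int r : rows) {
    W += w[r];
    if (classify) cw[(int)y[r]] += w[r]; else Sy += w[r] * y[r];
  }
  if (classify) {
    if (W > 0) for (int k = 0; k < K; k++) cw[k] /= W;
    T.dist.push_back(cw);
    T.value.push_back(0.0);
  } else {
    T.dist.push_back(std::vector<double>());
    T.value.push_back(W > 0 ? Sy / W : 0.0);
  }
  return (int)T.feature.size() - 1;
}

// [[Rcpp::export(name = ".cart_grow")]]
List cart_grow(NumericMatrix X, NumericVector y, NumericVector w,
               bool classify, int n_class, int max_splits, int min_leaf) {
  int n = X.nrow();
  if (n == 0) stop("empty training set");
  TreeBuild T;
  std::priority_queue<SplitInfo> pq;
  int uid = 0;

  std::vector<int> all(n);
  for (int i = 0; i < n; i++) all[i] = i;
  int root = add_leaf(T, y, w, all, classify, n_class);

  auto enqueue = [&](int node, const std::vector<int>& rows) {
    int bf; double bt, bgain;
    if (!best_split(X, y, w, rows, classify, n_class, min_leaf, bf, bt, bgain))
      return;
    SplitInfo s; s.gain = bgain; s.node = node; s.feature = bf;
    s.threshold = bt; s.uid = uid++;
    for (int r : rows) (X(r, bf) <= bt ? s.left_rows : s.right_rows).push_back(r);
    pq.push(std::move(s));
  };
  enqueue(root, all);

  int splits = 0;
  while (splits < max_splits && !pq.empty()) {
    SplitInfo s = pq.top(); pq.pop();
    int nl = add_leaf(T, y, w, s.left_rows, classify, n_class);
    int nr = add_leaf(T, y, w, s.right_rows, classify, n_class);
    T.feature[s.node] = s.feature;
    T.threshold[s.node] = s.threshold;
    T.left[s.node] = nl; T.right[s.node] = nr;
    splits++;
    if (splits >= max_splits) break;
    enqueue(nl, s.left_rows);
    enqueue(nr, s.right_rows);
  }

  int m = T.feature.size();
  IntegerVector feat(m), le(m), ri(m);
  NumericVector thr(m), val(m);
  for (int i = 0; i < m; i++) {
    feat[i] = T.feature[i]; le[i] = T.left[i]; ri[i] = T.right[i];
    thr[i] = T.threshold[i]; val[i] = T.value[i];
  }
  List out = List::create(_["feature"] = feat, _["threshold"] = thr,
                          _["left"] = le, _["right"] = ri, _["value"] = val,
                          _["classify"] = classify, _["n_class"] = n_class);
  if (classify) {
    NumericMatrix D(m, n_class);
    for (int i = 0; i < m; i++)
      if (!T.dist[i].empty())
        for (int k = 0; k < n_class; k++) D(i, k) = T.dist[i][k];
    out["dist"] = D;
  }
  return out;
}

// [[Rcpp::export(name = ".cart_predict")]]
NumericMatrix cart_predict(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feature"], le = tree["left"], ri = tree["right"];
  NumericVector thr = tree["threshold"], val = tree["value"];
  bool classify = tree["classify"];
  int K = tree["n_class"];
  NumericMatrix D;
  if (classify) D = as<NumericMatrix>(tree["dist"]);
  int n = X.nrow();
  NumericMatrix out(n, classify ? K : 1);
  for (int i = 0; i < n; i++) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? le[node] : ri[node];
    if (classify) for (int k = 0; k < K; k++) out(i, k) = D(node, k);
    else out(i, 0) = val[node];
  }
  return out;
}
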