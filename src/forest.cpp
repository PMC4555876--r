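// Bagged regression-tree ensemble (random forest) used to predict the
// dasymetric weighting layer: CART variance-reduction splits, `mtry` random
// covariate subsetting per node, bootstrap bagging, out-of-bag (OOB) error
// and OOB permutation importance. All randomness comes from R's RNG so a
// set.seed() on the R side makes fits bit-reproducible.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;       // split covariate (0-based), -1 for leaf
  std::vector<double> val;    // split threshold; x <= val goes left
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> pred;   // node mean of responses
};

inline int rand_int(int n) {
  // integer in [0, n) via R's uniform RNG
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// sample `m` distinct values from 0..p-1 (partial Fisher-Yates)
void sample_vars(int p, int m, std::vector<int>& pool, std::vector<int>& out) {
  for (int i = 0; i < p; ++i) pool[i] = i;
  out.resize(m);
  for (int i = 0; i < m; ++i) {
    int j = i + rand_int(p - i);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct NodeJob { int node, lo, hi; };

// grow one tree on rows idx[lo..hi) of X (bootstrap indices)
void grow_tree(const NumericMatrix& X, const NumericVector& y,
               std::vector<int>& idx, int n_boot, int mtry, int nodesize,
               Tree& tr) {
  const int p = X.ncol();
  std::vector<int> pool(p), vars;
  std::vector<std::pair<double, double> > xv;  // (x, y) pairs within a node
  std::vector<NodeJob> stack;

  tr.var.push_back(-1); tr.val.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0.0);
  stack.push_back(NodeJob{0, 0, n_boot});

  while (!stack.empty()) {
    NodeJob jb = stack.back(); stack.pop_back();
    int lo = jb.lo, hi = jb.hi, n = hi - lo;

    double sum = 0.0;
    for (int i = lo; i < hi; ++i) sum += y[idx[i]];
    double mean = sum / n;
    tr.pred[jb.node] = mean;

    bool pure = true;
    for (int i = lo + 1; i < hi; ++i)
      if (y[idx[i]] != y[idx[lo]]) { pure = false; break; }
    if (n <= nodesize || n < 2 || pure) continue;

    sample_vars(p, mtry, pool, vars);
    double best_gain = 0.0, best_thr = 0.0;
    int best_var = -1;

    for (int vi = 0; vi < (int)vars.size(); ++vi) {
      int v = vars[vi];
      xv.clear();
      for (int i = lo; i < hi; ++i)
        xv.push_back(std::make_pair(X(idx[i], v), y[idx[i]]));
      std::sort(xv.begin(), xv.end());
      if (xv.front().first == xv.back().first) continue;  // constant in node

      // maximize SL^2/nL + SR^2/nR (equivalent to minimizing total SSE)
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xv[i].second;
        if (xv[i].first == xv[i + 1].first) continue;
        double sr = sum - sl;
        int nl = i + 1, nr = n - nl;
        double gain = sl * sl / nl + sr * sr / nr - sum * sum / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = v;
          best_thr = 0.5 * (xv[i].first + xv[i + 1].first);
        }
      }
    }
    if (best_var < 0) continue;  // no valid split among sampled covariates

    // partition idx[lo..hi) in place
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X(idx[i], best_var) <= best_thr) std::swap(idx[mid++], idx[i]);
    if (mid == lo || mid == hi) continue;  // numeric degeneracy guard

    int l = (int)tr.var.size(), r = l + 1;
    for (int k = 0; k < 2; ++k) {
      tr.var.push_back(-1); tr.val.push_back(0.0);
      tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0.0);
    }
    tr.var[jb.node] = best_var;
    tr.val[jb.node] = best_thr;
    tr.left[jb.node] = l;
    tr.right[jb.node] = r;
    stack.push_back(NodeJob{l, lo, mid});
    stack.push_back(NodeJob{r, mid, hi});
  }
}

inline double tree_predict_row(const Tree& tr, const NumericMatrix& X, int row,
                               const int* remap_var = 0) {
  int node = 0;
  while (tr.var[node] >= 0) {
    int v = remap_var ? remap_var[tr.var[node]] : tr.var[node];
    node = (X(row, v) <= tr.val[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.pred[node];
}

// predict tree on OOB rows with column `perm_var` read through permuted rows
double tree_oob_mse_permuted(const Tree& tr, const NumericMatrix& X,
                             const NumericVector& y,
                             const std::vector<int>& oob,
                             const std::vector<int>& perm, int perm_var) {
  double sse = 0.0;
  int m = (int)oob.size();
  for (int i = 0; i < m; ++i) {
    int row = oob[i];
    int node = 0;
    while (tr.var[node] >= 0) {
      int v = tr.var[node];
      double xval = (v == perm_var) ? X(oob[perm[i]], v) : X(row, v);
      node = (xval <= tr.val[node]) ? tr.left[node] : tr.right[node];
    }
    double e = tr.pred[node] - y[row];
    sse += e * e;
  }
  return sse / m;
}

List tree_to_list(const Tree& tr) {
  return List::create(_["var"] = wrap(tr.var), _["val"] = wrap(tr.val),
                      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
                      _["pred"] = wrap(tr.pred));
}

Tree tree_from_list(const List& li) {
  Tree tr;
  tr.var = as<std::vector<int> >(li["var"]);
  tr.val = as<std::vector<double> >(li["val"]);
  tr.left = as<std::vector<int> >(li["left"]);
  tr.right = as<std::vector<int> >(li["right"]);
  tr.pred = as<std::vector<double> >(li["pred"]);
  return tr;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                int nodesize, bool keep_oob_tree_pred) {
  const int n = X.nrow(), p = X.ncol();
  if (n < 2) stop("need at least 2 observations");
  if (mtry < 1 || mtry > p) stop("mtry out of range");

  List trees(ntree);
  NumericVector imp(p);                 // mean increase in OOB MSE
  NumericVector oob_sum(n), oob_cnt(n);
  NumericMatrix oob_tree_pred;
  if (keep_oob_tree_pred) {
    oob_tree_pred = NumericMatrix(n, ntree);
    std::fill(oob_tree_pred.begin(), oob_tree_pred.end(), NA_REAL);
  }

  std::vector<int> idx(n), inbag(n), oob, perm;
  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int k = rand_int(n);
      idx[i] = k;
      inbag[k]++;
    }
    Tree tr;
    grow_tree(X, y, idx, n, mtry, nodesize, tr);
    trees[t] = tree_to_list(tr);

    oob.clear();
    for (int i = 0; i < n; ++i) if (inbag[i] == 0) oob.push_back(i);
    if (oob.empty()) continue;
    int m = (int)oob.size();

    double sse = 0.0;
    for (int i = 0; i < m; ++i) {
      double pr = tree_predict_row(tr, X, oob[i]);
      oob_sum[oob[i]] += pr;
      oob_cnt[oob[i]] += 1.0;
      if (keep_oob_tree_pred) oob_tree_pred(oob[i], t) = pr;
      double e = pr - y[oob[i]];
      sse += e * e;
    }
    double mse0 = sse / m;

    // permutation importance: shuffle each covariate's OOB values
    perm.resize(m);
    for (int v = 0; v < p; ++v) {
      for (int i = 0; i < m; ++i) perm[i] = i;
      for (int i = m - 1; i > 0; --i) std::swap(perm[i], perm[rand_int(i + 1)]);
      imp[v] += tree_oob_mse_permuted(tr, X, y, oob, perm, v) - mse0;
    }
  }
  for (int v = 0; v < p; ++v) imp[v] /= ntree;

  NumericVector oob_pred(n, NA_REAL);
  double oob_sse = 0.0;
  int oob_n = 0;
  for (int i = 0; i < n; ++i) {
    if (oob_cnt[i] > 0) {
      oob_pred[i] = oob_sum[i] / oob_cnt[i];
      double e = oob_pred[i] - y[i];
      oob_sse += e * e;
      oob_n++;
    }
  }

  List out = List::create(
      _["trees"] = trees, _["importance"] = imp, _["oob_pred"] = oob_pred,
      _["oob_mse"] = (oob_n > 0) ? oob_sse / oob_n : NA_REAL,
      _["n_oob"] = oob_n);
  if (keep_oob_tree_pred) out["oob_tree_pred"] = oob_tree_pred;
  return out;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += tree_predict_row(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}

// [[Rcpp::export(name = ".rf_predict_all_cpp")]]
NumericMatrix rf_predict_all_cpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, ntree);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out(i, t) = tree_predict_row(tr, X, i);
  }
  return out;
}
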