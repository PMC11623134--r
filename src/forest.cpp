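#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Gini impurity from class counts.
static inline double gini(const std::vector<int>& cnt, int n) {
  if (n <= 0) return 0.0;
  double s = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) {
    double p = (double)cnt[c] / (double)n;
    s += p * p;
  }
  return 1.0 - s;
}

struct SplitCandidate {
  bool found;
  double threshold;
  double decrease; // Gini(parent) - weighted Gini(children), over non-missing rows
};

// Best axis-aligned split of one column restricted to `rows`.
// Missing (NaN) entries are excluded from threshold enumeration; thresholds sit
// at midpoints between consecutive distinct values; ties keep the smallest
// threshold.
static SplitCandidate search_best_split(const double* col,
                                        const std::vector<int>& rows,
                                        const int* y, int n_classes) {
  SplitCandidate best = {false, NA_REAL, -1.0};
  std::vector<std::pair<double, int> > vy;
  vy.reserve(rows.size());
  for (size_t i = 0; i < rows.size(); ++i) {
    double v = col[rows[i]];
    if (!ISNAN(v)) vy.push_back(std::make_pair(v, y[rows[i]]));
  }
  int m = (int)vy.size();
  if (m < 2) return best;
  std::sort(vy.begin(), vy.end());
  if (vy.front().first == vy.back().first) return best;

  std::vector<int> tot(n_classes, 0), left(n_classes, 0);
  for (int i = 0; i < m; ++i) tot[vy[i].second]++;
  double g_parent = gini(tot, m);

  int nl = 0;
  for (int i = 0; i < m - 1; ++i) {
    left[vy[i].second]++;
    nl++;
    if (vy[i + 1].first > vy[i].first) {
      int nr = m - nl;
      std::vector<int> right(n_classes);
      for (int c = 0; c < n_classes; ++c) right[c] = tot[c] - left[c];
      double dec = g_parent
        - ((double)nl / m) * gini(left, nl)
        - ((double)nr / m) * gini(right, nr);
      if (!best.found || dec > best.decrease) {
        best.found = true;
        best.threshold = 0.5 * (vy[i].first + vy[i + 1].first);
        best.decrease = dec;
      }
    }
  }
  return best;
}

struct TreeBuilder {
  std::vector<int> split_var;   // 1-based; 0 = leaf
  std::vector<double> threshold;
  std::vector<int> left_child;  // 1-based node ids; 0 = none
  std::vector<int> right_child;
  std::vector<int> n_node;
  std::vector<int> pred;        // 1-based majority class (ties -> first class)
  std::vector<double> impurity;
  std::vector<double> decrease;     // on final partition, incl. routed missings

  int new_node() {
    split_var.push_back(0);
    threshold.push_back(NA_REAL);
    left_child.push_back(0);
    right_child.push_back(0);
    n_node.push_back(0);
    pred.push_back(0);
    impurity.push_back(0.0);
    decrease.push_back(0.0);
    return (int)split_var.size() - 1;
  }
};

// [[Rcpp::export]]
List grow_tree_cpp(NumericMatrix X, IntegerVector y, int n_classes,
                   int mtry, int min_node_size, int seed) {
  int n = X.nrow(), p = X.ncol();
  if (n < 1) stop("empty in-bag sample");
  if (mtry < 1 || mtry > p) stop("mtry must be in 1..p");
  std::vector<int> y0(n);
  for (int i = 0; i < n; ++i) {
    y0[i] = y[i] - 1;
    if (y0[i] < 0 || y0[i] >= n_classes) stop("class label out of range");
  }
  std::mt19937 gen((unsigned int)seed);
  std::vector<int> vars(p);

  TreeBuilder tb;
  int root = tb.new_node();
  std::vector<std::pair<int, std::vector<int> > > stack;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  stack.push_back(std::make_pair(root, all));

  while (!stack.empty()) {
    int node = stack.back().first;
    std::vector<int> rows = stack.back().second;
    stack.pop_back();
    int m = (int)rows.size();

    std::vector<int> cnt(n_classes, 0);
    for (int i = 0; i < m; ++i) cnt[y0[rows[i]]]++;
    int best_c = 0;
    for (int c = 1; c < n_classes; ++c) if (cnt[c] > cnt[best_c]) best_c = c;
    double g = gini(cnt, m);
    tb.n_node[node] = m;
    tb.pred[node] = best_c + 1;
    tb.impurity[node] = g;

    if (g <= 0.0 || m < 2 || m < min_node_size) continue;

    // draw mtry candidate variables without replacement, evaluate in
    // ascending index order so ties break to the lower variable index
    for (int j = 0; j < p; ++j) vars[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int r = j + (int)(gen() % (unsigned int)(p - j));
      std::swap(vars[j], vars[r]);
    }
    std::vector<int> cand(vars.begin(), vars.begin() + mtry);
    std::sort(cand.begin(), cand.end());

    int best_v = -1;
    SplitCandidate best = {false, NA_REAL, -1.0};
    for (size_t j = 0; j < cand.size(); ++j) {
      SplitCandidate s = search_best_split(&X(0, cand[j]), rows, y0.data(),
                                           n_classes);
      if (s.found && (!best.found || s.decrease > best.decrease)) {
        best = s;
        best_v = cand[j];
      }
    }
    if (!best.found) continue; // unsplittable node stays a leaf

    // partition; missing values go to the child with more (non-missing)
    // in-bag samples, ties to the left
    std::vector<int> lrows, rrows, narows;
    for (int i = 0; i < m; ++i) {
      double v = X(rows[i], best_v);
      if (ISNAN(v)) narows.push_back(rows[i]);
      else if (v <= best.threshold) lrows.push_back(rows[i]);
      else rrows.push_back(rows[i]);
    }
    if (!narows.empty()) {
      std::vector<int>& tgt = (lrows.size() >= rrows.size()) ? lrows : rrows;
      tgt.insert(tgt.end(), narows.begin(), narows.end());
    }
    if (lrows.empty() || rrows.empty()) continue; // degenerate; keep leaf

    std::vector<int> lc(n_classes, 0), rc(n_classes, 0);
    for (size_t i = 0; i < lrows.size(); ++i) lc[y0[lrows[i]]]++;
    for (size_t i = 0; i < rrows.size(); ++i) rc[y0[rrows[i]]]++;
    double dec = g
      - ((double)lrows.size() / m) * gini(lc, (int)lrows.size())
      - ((double)rrows.size() / m) * gini(rc, (int)rrows.size());

    tb.split_var[node] = best_v + 1;
    tb.threshold[node] = best.threshold;
    tb.decrease[node] = dec;

    int lid = tb.new_node();
    int rid = tb.new_node();
    tb.left_child[node] = lid + 1;
    tb.right_child[node] = rid + 1;
    // push right first so the left child is processed next (stable preorder)
    stack.push_back(std::make_pair(rid, rrows));
    stack.push_back(std::make_pair(lid, lrows));
  }

  return List::create(
    _["split_var"] = wrap(tb.split_var),
    _["threshold"] = wrap(tb.threshold),
    _["left"] = wrap(tb.left_child),
    _["right"] = wrap(tb.right_child),
    _["n_node"] = wrap(tb.n_node),
    _["pred"] = wrap(tb.pred),
    _["impurity"] = wrap(tb.impurity),
    _["decrease"] = wrap(tb.decrease));
}

// [[Rcpp::export]]
IntegerVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector split_var = tree["split_var"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  IntegerVector n_node = tree["n_node"];
  IntegerVector pred = tree["pred"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (split_var[node] > 0) {
      double v = X(i, split_var[node] - 1);
      int l = left[node] - 1, r = right[node] - 1;
      if (ISNAN(v)) {
        node = (n_node[l] >= n_node[r]) ? l : r;
      } else {
        node = (v <= threshold[node]) ? l : r;
      }
    }
    out[i] = pred[node];
  }
  return out;
}

// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, IntegerVector y, IntegerVector candidates,
                    int n_classes) {
  int n = X.nrow();
  std::vector<int> rows(n), y0(n);
  for (int i = 0; i < n; ++i) { rows[i] = i; y0[i] = y[i] - 1; }
  std::vector<int> cnt(n_classes, 0);
  for (int i = 0; i < n; ++i) cnt[y0[i]]++;
  if (gini(cnt, n) <= 0.0) return List::create(); // pure node
  std::vector<int> cand(candidates.begin(), candidates.end());
  std::sort(cand.begin(), cand.end());
  int best_v = -1;
  SplitCandidate best = {false, NA_REAL, -1.0};
  for (size_t j = 0; j < cand.size(); ++j) {
    SplitCandidate s = search_best_split(&X(0, cand[j] - 1), rows, y0.data(),
                                         n_classes);
    if (s.found && (!best.found || s.decrease > best.decrease)) {
      best = s;
      best_v = cand[j];
    }
  }
  if (!best.found) return List::create();
  return List::create(_["variable_index"] = best_v,
                      _["threshold"] = best.threshold,
                      _["impurity_decrease"] = best.decrease);
}
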