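// Exact-greedy second-order regression-tree builder: the hot path of the
// boosted ensemble. Split gain and leaf weights follow the regularized
// second-order objective: w* = -G/(H + lambda),
// gain = 1/2 [ GL^2/(HL+l) + GR^2/(HR+l) - (GL+GR)^2/(HL+HR+l) ] - gamma.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct SplitResult {
  int feature;      // 1-based; 0 = none
  double threshold;
  double gain;
};

// Exact greedy scan over sorted unique values of each candidate feature.
// Ties: lower feature index, then lower threshold (first strict maximum
// found while scanning features ascending / thresholds ascending wins).
static SplitResult findBestSplit(const NumericMatrix& X,
                                 const NumericVector& g,
                                 const NumericVector& h,
                                 const std::vector<int>& rows,
                                 const std::vector<int>& cols,
                                 double lambda, double gamma,
                                 double min_child_weight) {
  SplitResult best{0, 0.0, 0.0};
  const int n = (int)rows.size();
  if (n < 2) return best;
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  const double parent = G * G / (H + lambda);

  std::vector<std::pair<double, int>> vals(n);
  for (int f : cols) {
    for (int i = 0; i < n; ++i)
      vals[i] = std::make_pair(X(rows[i], f), rows[i]);
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      GL += g[vals[i].second];
      HL += h[vals[i].second];
      if (vals[i].first == vals[i + 1].first) continue;  // not a boundary
      const double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain = 0.5 * (GL * GL / (HL + lambda) +
                                 GR * GR / (HR + lambda) - parent) - gamma;
      if (gain > best.gain && gain > 0.0) {
        const double thr = 0.5 * (vals[i].first + vals[i + 1].first);
        // guard against midpoint rounding onto a value: require a real
        // partition under the predicate x < thr
        if (vals[i].first < thr && !(vals[i + 1].first < thr)) {
          best.feature = f + 1;
          best.threshold = thr;
          best.gain = gain;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_best_split(NumericMatrix X, NumericVector g, NumericVector h,
                    IntegerVector rows, IntegerVector cols,
                    double lambda, double gamma, double min_child_weight) {
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> cv(cols.begin(), cols.end());
  for (int& r : rv) --r;  // to 0-based
  for (int& c : cv) --c;
  SplitResult s = findBestSplit(X, g, h, rv, cv, lambda, gamma,
                                min_child_weight);
  return List::create(_["feature"] = s.feature, _["threshold"] = s.threshold,
                      _["gain"] = s.gain);
}

struct TreeNode {
  int feature;       // 1-based, 0 = leaf
  double threshold;
  int left, right;   // 1-based row indices into the node table
  double weight;     // leaf weight (filled for leaves)
  double gain;       // split gain (internal nodes)
  double cover;      // Hessian sum at the node
};

static void growNode(const NumericMatrix& X, const NumericVector& g,
                     const NumericVector& h, std::vector<int> rows,
                     const std::vector<int>& cols, int depth, int max_depth,
                     double lambda, double gamma, double min_child_weight,
                     std::vector<TreeNode>& nodes, int nodeIdx) {
  double G = 0.0, H = 0.0;
  for (int r : rows) { G += g[r]; H += h[r]; }
  nodes[nodeIdx].cover = H;
  SplitResult s{0, 0.0, 0.0};
  if (depth < max_depth && (int)rows.size() >= 2)
    s = findBestSplit(X, g, h, rows, cols, lambda, gamma, min_child_weight);
  if (s.feature == 0) {
    nodes[nodeIdx].feature = 0;
    nodes[nodeIdx].weight = -G / (H + lambda);
    return;
  }
  std::vector<int> leftRows, rightRows;
  for (int r : rows) {
    if (X(r, s.feature - 1) < s.threshold) leftRows.push_back(r);
    else rightRows.push_back(r);
  }
  nodes[nodeIdx].feature = s.feature;
  nodes[nodeIdx].threshold = s.threshold;
  nodes[nodeIdx].gain = s.gain;
  nodes.push_back(TreeNode{0, 0, 0, 0, 0, 0, 0});
  nodes.push_back(TreeNode{0, 0, 0, 0, 0, 0, 0});
  const int li = (int)nodes.size() - 2, ri = (int)nodes.size() - 1;
  nodes[nodeIdx].left = li + 1;
  nodes[nodeIdx].right = ri + 1;
  growNode(X, g, h, leftRows, cols, depth + 1, max_depth, lambda, gamma,
           min_child_weight, nodes, li);
  growNode(X, g, h, rightRows, cols, depth + 1, max_depth, lambda, gamma,
           min_child_weight, nodes, ri);
}

// [[Rcpp::export]]
NumericMatrix cpp_build_tree(NumericMatrix X, NumericVector g, NumericVector h,
                             IntegerVector rows, IntegerVector cols,
                             int max_depth, double lambda, double gamma,
                             double min_child_weight) {
  std::vector<int> rv(rows.begin(), rows.end());
  std::vector<int> cv(cols.begin(), cols.end());
  for (int& r : rv) --r;
  for (int& c : cv) --c;
  std::vector<TreeNode> nodes;
  nodes.push_back(TreeNode{0, 0, 0, 0, 0, 0, 0});
  growNode(X, g, h, rv, cv, 0, max_depth, lambda, gamma, min_child_weight,
           nodes, 0);
  NumericMatrix out((int)nodes.size(), 7);
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "weight", "gain", "cover");
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].weight;
    out(i, 5) = nodes[i].gain;
    out(i, 6) = nodes[i].cover;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(NumericMatrix nodes, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int cur = 0;
    while ((int)nodes(cur, 0) != 0) {
      const int f = (int)nodes(cur, 0) - 1;
      cur = (X(i, f) < nodes(cur, 1)) ? (int)nodes(cur, 2) - 1
                                      : (int)nodes(cur, 3) - 1;
    }
    out[i] = nodes(cur, 4);
  }
  return out;
}
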