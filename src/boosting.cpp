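#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Regularized gradient tree boosting, binary logistic objective.
// Trees are grown by exact greedy search over all features and all midpoints
// between consecutive distinct sorted values; split gain is the second-order
// formula  1/2 [ GL^2/(HL+l) + GR^2/(HR+l) - (GL+GR)^2/(HL+HR+l) ] - gamma.
// A split is accepted only if gain > 0 and both children have hessian sum
// >= min_child_weight. Leaf weight = -G/(H+l). Ties broken toward the lowest
// feature index, then the lowest threshold (guaranteed by the ascending scan
// with a strict improvement test).

struct Node {
  int feature;       // 1-based; 0 for leaf
  double threshold;
  int left, right;   // 1-based node indices; 0 for leaf
  double weight;     // leaf weight (0 for internal)
  double hess_sum;
  double grad_sum;
  double gain;       // split gain (NA-like 0 for leaf)
  int depth;
  int n_instances;
};

struct SplitResult {
  bool found;
  int feature;       // 0-based
  double threshold;
  double gain;
};

static SplitResult find_best_split(const NumericMatrix& X,
                                   const NumericVector& g,
                                   const NumericVector& h,
                                   const std::vector<int>& idx,
                                   double lambda, double gamma,
                                   double min_child_weight) {
  SplitResult best = {false, -1, 0.0, 0.0};
  const int m = idx.size(), d = X.ncol();
  if (m < 2) return best;
  double G = 0, H = 0;
  for (int t = 0; t < m; ++t) { G += g[idx[t]]; H += h[idx[t]]; }
  const double parent = G * G / (H + lambda);
  std::vector<int> ord(m);
  for (int j = 0; j < d; ++j) {
    for (int t = 0; t < m; ++t) ord[t] = idx[t];
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
    double GL = 0, HL = 0;
    for (int t = 0; t < m - 1; ++t) {
      GL += g[ord[t]]; HL += h[ord[t]];
      double xlo = X(ord[t], j), xhi = X(ord[t + 1], j);
      if (xlo == xhi) continue;
      double HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double GR = G - GL;
      double thr = (xlo + xhi) / 2.0;
      double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                           parent) - gamma;
      if (gain > best.gain || !best.found) {
        if (gain > 0 && (!best.found || gain > best.gain)) {
          best.found = true; best.feature = j; best.threshold = thr;
          best.gain = gain;
        }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List gtb_best_split_cpp(NumericMatrix X, NumericVector g, NumericVector h,
                        double lambda, double gamma, double min_child_weight) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  SplitResult s = find_best_split(X, g, h, idx, lambda, gamma, min_child_weight);
  if (!s.found) return List::create(Named("found") = false);
  return List::create(Named("found") = true,
                      Named("feature") = s.feature + 1,
                      Named("threshold") = s.threshold,
                      Named("gain") = s.gain);
}

static int grow_node(std::vector<Node>& nodes, const NumericMatrix& X,
                     const NumericVector& g, const NumericVector& h,
                     std::vector<int>& idx, int depth, int max_depth,
                     double lambda, double gamma, double min_child_weight,
                     std::vector<int>& leaf_of) {
  double G = 0, H = 0;
  for (size_t t = 0; t < idx.size(); ++t) { G += g[idx[t]]; H += h[idx[t]]; }
  Node nd = {0, 0.0, 0, 0, 0.0, H, G, 0.0, depth, (int)idx.size()};
  int me = nodes.size();
  nodes.push_back(nd);
  SplitResult s = {false, -1, 0.0, 0.0};
  if (depth < max_depth && idx.size() >= 2)
    s = find_best_split(X, g, h, idx, lambda, gamma, min_child_weight);
  if (s.found) {
    std::vector<int> li, ri;
    for (size_t t = 0; t < idx.size(); ++t) {
      if (X(idx[t], s.feature) < s.threshold) li.push_back(idx[t]);
      else ri.push_back(idx[t]);
    }
    int l = grow_node(nodes, X, g, h, li, depth + 1, max_depth, lambda, gamma,
                      min_child_weight, leaf_of);
    int r = grow_node(nodes, X, g, h, ri, depth + 1, max_depth, lambda, gamma,
                      min_child_weight, leaf_of);
    nodes[me].feature = s.feature + 1;
    nodes[me].threshold = s.threshold;
    nodes[me].left = l + 1;
    nodes[me].right = r + 1;
    nodes[me].gain = s.gain;
  } else {
    nodes[me].weight = -G / (H + lambda);
    for (size_t t = 0; t < idx.size(); ++t) leaf_of[idx[t]] = me;
  }
  return me;
}

static NumericMatrix nodes_to_matrix(const std::vector<Node>& nodes) {
  NumericMatrix M(nodes.size(), 9);
  colnames(M) = CharacterVector::create("feature", "threshold", "left", "right",
                                        "weight", "hess_sum", "gain", "depth",
                                        "n_instances");
  for (size_t i = 0; i < nodes.size(); ++i) {
    M(i, 0) = nodes[i].feature;  M(i, 1) = nodes[i].threshold;
    M(i, 2) = nodes[i].left;     M(i, 3) = nodes[i].right;
    M(i, 4) = nodes[i].weight;   M(i, 5) = nodes[i].hess_sum;
    M(i, 6) = nodes[i].gain;     M(i, 7) = nodes[i].depth;
    M(i, 8) = nodes[i].n_instances;
  }
  return M;
}

static double tree_value(const NumericMatrix& tree, const NumericMatrix& X,
                         int row) {
  int node = 0;
  while ((int)tree(node, 0) != 0) {
    int f = (int)tree(node, 0) - 1;
    node = (X(row, f) < tree(node, 1)) ? (int)tree(node, 2) - 1
                                       : (int)tree(node, 3) - 1;
  }
  return tree(node, 4);
}

// [[Rcpp::export]]
List gtb_fit_cpp(NumericMatrix X, IntegerVector y, double eta, int max_depth,
                 double min_child_weight, double gamma, int n_rounds,
                 double lambda) {
  const int n = X.nrow();
  double pos = 0;
  for (int i = 0; i < n; ++i) pos += y[i];
  const double prior = pos / n;
  const double base = std::log(prior / (1.0 - prior));
  NumericVector margin(n, base);
  List trees(n_rounds);
  NumericVector train_loss(n_rounds);
  std::vector<int> leaf_of(n);
  for (int t = 0; t < n_rounds; ++t) {
    NumericVector g(n), h(n);
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      g[i] = p - y[i];
      h[i] = p * (1.0 - p);
    }
    std::vector<Node> nodes;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    grow_node(nodes, X, g, h, idx, 0, max_depth, lambda, gamma,
              min_child_weight, leaf_of);
    NumericMatrix M = nodes_to_matrix(nodes);
    trees[t] = M;
    for (int i = 0; i < n; ++i) margin[i] += eta * nodes[leaf_of[i]].weight;
    double ll = 0;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-margin[i]));
      p = std::min(std::max(p, 1e-15), 1.0 - 1e-15);
      ll += y[i] ? -std::log(p) : -std::log(1.0 - p);
    }
    train_loss[t] = ll / n;
  }
  return List::create(Named("base") = base, Named("trees") = trees,
                      Named("train_loss") = train_loss);
}

// [[Rcpp::export]]
NumericVector gtb_margin_cpp(List trees, double base, double eta,
                             NumericMatrix X) {
  const int n = X.nrow();
  NumericVector margin(n, base);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) margin[i] += eta * tree_value(tree, X, i);
  }
  return margin;
}
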