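// Double-precision tree-ensemble prediction and TreeSHAP attribution.
//
// Trees arrive as a flat table (one row per node over all trees) produced
// from the trained forest: for each node its tree id, children, split
// feature/threshold, leaf value and node sample weight (cover). Predictions
// average nothing here -- the ensemble is summed and the caller owns the
// base score -- so base + rowSums(contributions) equals the prediction to
// machine precision.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> left, right, feature; // feature = -1 for leaf
  std::vector<double> threshold, value, cover;
};

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

int tree_depth(const Tree& t, int node) {
  if (t.feature[node] < 0) return 1;
  int dl = tree_depth(t, t.left[node]);
  int dr = tree_depth(t, t.right[node]);
  return 1 + (dl > dr ? dl : dr);
}

double predict_one(const Tree& t, const double* x) {
  int node = 0;
  while (t.feature[node] >= 0) {
    node = x[t.feature[node]] < t.threshold[node] ? t.left[node]
                                                  : t.right[node];
  }
  return t.value[node];
}

double tree_mean(const Tree& t, int node) {
  if (t.feature[node] < 0) return t.value[node];
  int l = t.left[node], r = t.right[node];
  return (t.cover[l] * tree_mean(t, l) + t.cover[r] * tree_mean(t, r)) /
         t.cover[node];
}

void extend_path(PathElement* unique_path, int unique_depth,
                 double zero_fraction, double one_fraction,
                 int feature_index) {
  unique_path[unique_depth].feature_index = feature_index;
  unique_path[unique_depth].zero_fraction = zero_fraction;
  unique_path[unique_depth].one_fraction = one_fraction;
  unique_path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; i--) {
    unique_path[i + 1].pweight += one_fraction * unique_path[i].pweight *
                                  (i + 1) / (double)(unique_depth + 1);
    unique_path[i].pweight = zero_fraction * unique_path[i].pweight *
                             (unique_depth - i) / (double)(unique_depth + 1);
  }
}

void unwind_path(PathElement* unique_path, int unique_depth, int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = unique_path[i].pweight;
      unique_path[i].pweight = next_one_portion * (unique_depth + 1) /
                               (double)((i + 1) * one_fraction);
      next_one_portion = tmp - unique_path[i].pweight * zero_fraction *
                                   (unique_depth - i) /
                                   (double)(unique_depth + 1);
    } else {
      unique_path[i].pweight = (unique_path[i].pweight * (unique_depth + 1)) /
                               (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    unique_path[i].feature_index = unique_path[i + 1].feature_index;
    unique_path[i].zero_fraction = unique_path[i + 1].zero_fraction;
    unique_path[i].one_fraction = unique_path[i + 1].one_fraction;
  }
}

double unwound_path_sum(const PathElement* unique_path, int unique_depth,
                        int path_index) {
  const double one_fraction = unique_path[path_index].one_fraction;
  const double zero_fraction = unique_path[path_index].zero_fraction;
  double next_one_portion = unique_path[unique_depth].pweight;
  double total = 0;
  if (one_fraction != 0) {
    for (int i = unique_depth - 1; i >= 0; --i) {
      const double tmp =
          next_one_portion / (double)((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = unique_path[i].pweight -
                         tmp * zero_fraction * (unique_depth - i);
    }
  } else {
    for (int i = unique_depth - 1; i >= 0; --i) {
      total += unique_path[i].pweight / (zero_fraction * (unique_depth - i));
    }
  }
  return total * (unique_depth + 1);
}

void tree_shap_recursive(const Tree& t, const double* x, double* phi,
                         int node, int unique_depth,
                         PathElement* parent_unique_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement* unique_path = parent_unique_path + unique_depth + 1;
  std::copy(parent_unique_path, parent_unique_path + unique_depth + 1,
            unique_path);
  extend_path(unique_path, unique_depth, parent_zero_fraction,
              parent_one_fraction, parent_feature_index);

  if (t.feature[node] < 0) { // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(unique_path, unique_depth, i);
      const PathElement& el = unique_path[i];
      phi[el.feature_index] +=
          w * (el.one_fraction - el.zero_fraction) * t.value[node];
    }
    return;
  }

  const int split_feature = t.feature[node];
  const int hot_index = x[split_feature] < t.threshold[node] ? t.left[node]
                                                             : t.right[node];
  const int cold_index =
      hot_index == t.left[node] ? t.right[node] : t.left[node];
  const double w = t.cover[node];
  const double hot_zero_fraction = t.cover[hot_index] / w;
  const double cold_zero_fraction = t.cover[cold_index] / w;
  double incoming_zero_fraction = 1;
  double incoming_one_fraction = 1;

  // undo a previous split on the same feature, if any
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index) {
    if (unique_path[path_index].feature_index == split_feature) break;
  }
  if (path_index != unique_depth + 1) {
    incoming_zero_fraction = unique_path[path_index].zero_fraction;
    incoming_one_fraction = unique_path[path_index].one_fraction;
    unwind_path(unique_path, unique_depth, path_index);
    unique_depth -= 1;
  }

  tree_shap_recursive(t, x, phi, hot_index, unique_depth + 1, unique_path,
                      hot_zero_fraction * incoming_zero_fraction,
                      incoming_one_fraction, split_feature);
  tree_shap_recursive(t, x, phi, cold_index, unique_depth + 1, unique_path,
                      cold_zero_fraction * incoming_zero_fraction, 0.0,
                      split_feature);
}

std::vector<Tree> build_trees(const IntegerVector& tree_id,
                              const IntegerVector& left,
                              const IntegerVector& right,
                              const IntegerVector& feature,
                              const NumericVector& threshold,
                              const NumericVector& value,
                              const NumericVector& cover) {
  int ntree = 0;
  for (int i = 0; i < tree_id.size(); ++i)
    if (tree_id[i] + 1 > ntree) ntree = tree_id[i] + 1;
  std::vector<Tree> trees(ntree);
  for (int i = 0; i < tree_id.size(); ++i) {
    Tree& t = trees[tree_id[i]];
    t.left.push_back(left[i]);
    t.right.push_back(right[i]);
    t.feature.push_back(feature[i]);
    t.threshold.push_back(threshold[i]);
    t.value.push_back(value[i]);
    t.cover.push_back(cover[i]);
  }
  return trees;
}

} // namespace

// [[Rcpp::export]]
NumericVector ensemble_predict_cpp(IntegerVector tree_id, IntegerVector left,
                                   IntegerVector right, IntegerVector feature,
                                   NumericVector threshold,
                                   NumericVector value, NumericVector cover,
                                   NumericMatrix X, double base_score,
                                   double scale) {
  std::vector<Tree> trees =
      build_trees(tree_id, left, right, feature, threshold, value, cover);
  const int n = X.nrow(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    double s = 0;
    for (size_t k = 0; k < trees.size(); ++k)
      s += predict_one(trees[k], row.data());
    out[i] = base_score + scale * s;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix treeshap_cpp(IntegerVector tree_id, IntegerVector left,
                           IntegerVector right, IntegerVector feature,
                           NumericVector threshold, NumericVector value,
                           NumericVector cover, NumericMatrix X,
                           double base_score, double scale) {
  std::vector<Tree> trees =
      build_trees(tree_id, left, right, feature, threshold, value, cover);
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p + 1); // last column: expected value (bias)
  double bias = base_score;
  int maxd = 0;
  for (size_t k = 0; k < trees.size(); ++k) {
    bias += scale * tree_mean(trees[k], 0);
    int d = tree_depth(trees[k], 0);
    if (d > maxd) maxd = d;
  }
  const int path_len = (maxd + 2) * (maxd + 3) / 2;
  std::vector<PathElement> paths(path_len);
  std::vector<double> row(p), phi(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (size_t k = 0; k < trees.size(); ++k) {
      tree_shap_recursive(trees[k], row.data(), phi.data(), 0, 0,
                          paths.data(), 1.0, 1.0, -1);
    }
    for (int j = 0; j < p; ++j) out(i, j) = scale * phi[j];
    out(i, p) = bias;
  }
  return out;
}
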