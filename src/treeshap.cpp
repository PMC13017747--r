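// Exact path-dependent TreeSHAP for additive tree ensembles, in double
// precision (the boosters' own attribution passes run in single
// precision, which is too coarse for strict local-accuracy checks).
// The recursion follows the standard polynomial-time algorithm for
// conditional-expectation Shapley values on trees, with node "cover"
// (training hessian weight) defining the conditional split fractions.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct PathElem {
  int d;        // feature index on the path (-1 for the root placeholder)
  double z;     // fraction of zero (background) paths that flow through
  double o;     // fraction of one (foreground) paths that flow through
  double w;     // permutation weight held by this path prefix
};

static void extend_path(std::vector<PathElem> &m, double pz, double po,
                        int pi) {
  int l = static_cast<int>(m.size());
  PathElem e; e.d = pi; e.z = pz; e.o = po; e.w = (l == 0 ? 1.0 : 0.0);
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

static void unwind_path(std::vector<PathElem> &m, int path_index) {
  int l = static_cast<int>(m.size()) - 1;
  double one_fraction = m[path_index].o;
  double zero_fraction = m[path_index].z;
  double next_one_portion = m[l].w;
  for (int i = l - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      double tmp = m[i].w;
      m[i].w = next_one_portion * (l + 1) /
               static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - m[i].w * zero_fraction * (l - i) /
                         static_cast<double>(l + 1);
    } else {
      m[i].w = m[i].w * (l + 1) /
               (zero_fraction * static_cast<double>(l - i));
    }
  }
  for (int i = path_index; i < l; ++i) {
    m[i].d = m[i + 1].d;
    m[i].z = m[i + 1].z;
    m[i].o = m[i + 1].o;
  }
  m.pop_back();
}

static double unwound_path_sum(const std::vector<PathElem> &m,
                               int path_index) {
  int l = static_cast<int>(m.size()) - 1;
  double one_fraction = m[path_index].o;
  double zero_fraction = m[path_index].z;
  double next_one_portion = m[l].w;
  double total = 0;
  if (one_fraction != 0) {
    for (int i = l - 1; i >= 0; --i) {
      double tmp = next_one_portion * (l + 1) /
                   static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = m[i].w - tmp * zero_fraction * (l - i) /
                         static_cast<double>(l + 1);
    }
  } else {
    for (int i = l - 1; i >= 0; --i) {
      total += m[i].w * (l + 1) /
               (zero_fraction * static_cast<double>(l - i));
    }
  }
  return total;
}

struct Tree {
  const int *feature;   // -1 for leaves
  const double *split;
  const int *yes, *no, *missing;  // child node indices, -1 for leaves
  const double *value;  // leaf value (0 for internal)
  const double *cover;
};

static void tree_shap_recursive(const Tree &tr, const double *x,
                                double *phi, int node,
                                std::vector<PathElem> m, double pz,
                                double po, int pi) {
  extend_path(m, pz, po, pi);
  if (tr.feature[node] < 0) {  // leaf
    double v = tr.value[node];
    for (int i = 1; i < static_cast<int>(m.size()); ++i) {
      double w = unwound_path_sum(m, i);
      phi[m[i].d] += w * (m[i].o - m[i].z) * v;
    }
    return;
  }
  int f = tr.feature[node];
  double xv = x[f];
  int hot, cold;
  if (ISNAN(xv)) {
    hot = tr.missing[node];
  } else if (static_cast<float>(xv) < static_cast<float>(tr.split[node])) {
    hot = tr.yes[node];
  } else {
    hot = tr.no[node];
  }
  cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  double w = tr.cover[node];
  double hot_z = tr.cover[hot] / w;
  double cold_z = tr.cover[cold] / w;
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (int i = 1; i < static_cast<int>(m.size()); ++i) {
    if (m[i].d == f) { k = i; break; }
  }
  if (k >= 0) {
    iz = m[k].z; io = m[k].o;
    unwind_path(m, k);
  }
  tree_shap_recursive(tr, x, phi, hot, m, iz * hot_z, io, f);
  tree_shap_recursive(tr, x, phi, cold, m, iz * cold_z, 0.0, f);
}

static double tree_expected_value(const Tree &tr, int node) {
  if (tr.feature[node] < 0) return tr.value[node];
  double w = tr.cover[node];
  return (tr.cover[tr.yes[node]] / w) *
           tree_expected_value(tr, tr.yes[node]) +
         (tr.cover[tr.no[node]] / w) *
           tree_expected_value(tr, tr.no[node]);
}

static Tree make_tree(const List &t) {
  Tree tr;
  tr.feature = INTEGER(as<IntegerVector>(t["feature"]));
  tr.split = REAL(as<NumericVector>(t["split"]));
  tr.yes = INTEGER(as<IntegerVector>(t["yes"]));
  tr.no = INTEGER(as<IntegerVector>(t["no"]));
  tr.missing = INTEGER(as<IntegerVector>(t["missing"]));
  tr.value = REAL(as<NumericVector>(t["value"]));
  tr.cover = REAL(as<NumericVector>(t["cover"]));
  return tr;
}

// [[Rcpp::export(name = ".treeshap_cpp")]]
NumericMatrix treeshap_cpp(List trees, NumericMatrix X, int n_features,
                           double base_offset) {
  int n = X.nrow();
  NumericMatrix out(n, n_features + 1);  // last column = expected value
  double expected = base_offset;
  std::vector<Tree> parsed;
  parsed.reserve(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    parsed.push_back(make_tree(as<List>(trees[t])));
    expected += tree_expected_value(parsed.back(), 0);
  }
  std::vector<double> x(X.ncol());
  std::vector<double> phi(n_features + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < X.ncol(); ++j) x[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (size_t t = 0; t < parsed.size(); ++t) {
      tree_shap_recursive(parsed[t], x.data(), phi.data(), 0,
                          std::vector<PathElem>(), 1.0, 1.0, -1);
    }
    for (int j = 0; j < n_features; ++j) out(i, j) = phi[j];
    out(i, n_features) = expected;
  }
  return out;
}

// [[Rcpp::export(name = ".tree_margin_cpp")]]
NumericVector tree_margin_cpp(List trees, NumericMatrix X,
                              double base_offset) {
  int n = X.nrow();
  NumericVector out(n);
  std::vector<Tree> parsed;
  parsed.reserve(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    parsed.push_back(make_tree(as<List>(trees[t])));
  }
  for (int i = 0; i < n; ++i) {
    double s = base_offset;
    for (size_t t = 0; t < parsed.size(); ++t) {
      const Tree &tr = parsed[t];
      int node = 0;
      while (tr.feature[node] >= 0) {
        double xv = X(i, tr.feature[node]);
        if (ISNAN(xv)) node = tr.missing[node];
        else if (static_cast<float>(xv) < static_cast<float>(tr.split[node])) node = tr.yes[node];
        else node = tr.no[node];
      }
      s += tr.value[node];
    }
    out[i] = s;
  }
  return out;
}
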