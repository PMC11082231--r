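#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact path-dependent TreeSHAP (Lundberg-style polynomial algorithm) in
// double precision over a parsed tree ensemble. Internal-node "cover"
// weights define the background distribution; local accuracy
// (sum(phi) + E[f] = f(x)) then holds to floating-point round-off.

struct PathElem {
  int d;       // feature index of the split that brought us here (-1 at root)
  double z;    // fraction of zero (cold) paths flowing through
  double o;    // fraction of one (hot) paths flowing through
  double w;    // permutation weight
};

static void extend_path(std::vector<PathElem> &m, double pz, double po, int pi) {
  const int l = static_cast<int>(m.size());
  PathElem e; e.d = pi; e.z = pz; e.o = po; e.w = (l == 0) ? 1.0 : 0.0;
  m.push_back(e);
  for (int i = l - 1; i >= 0; --i) {
    m[i + 1].w += po * m[i].w * (i + 1) / static_cast<double>(l + 1);
    m[i].w = pz * m[i].w * (l - i) / static_cast<double>(l + 1);
  }
}

static void unwind_path(std::vector<PathElem> &m, int idx) {
  const int l = static_cast<int>(m.size()) - 1;
  const double o = m[idx].o, z = m[idx].z;
  double n = m[l].w;
  for (int i = l - 1; i >= 0; --i) {
    if (o != 0.0) {
      const double tmp = m[i].w;
      m[i].w = n * (l + 1) / (static_cast<double>(i + 1) * o);
      n = tmp - m[i].w * z * (l - i) / static_cast<double>(l + 1);
    } else {
      m[i].w = m[i].w * (l + 1) / (z * static_cast<double>(l - i));
    }
  }
  for (int i = idx; i < l; ++i) {
    m[i].d = m[i + 1].d; m[i].z = m[i + 1].z; m[i].o = m[i + 1].o;
  }
  m.pop_back();
}

// Total permutation weight if the extension at idx were unwound
// (sum of pweights of the unwound path).
static double unwound_sum(const std::vector<PathElem> &m, int idx) {
  std::vector<PathElem> cp(m);
  unwind_path(cp, idx);
  double s = 0.0;
  for (size_t i = 0; i < cp.size(); ++i) s += cp[i].w;
  return s;
}

struct Tree {
  IntegerVector yes, no, feat;  // feat = -1 for leaves
  NumericVector split, cover, value;
};

static void shap_recurse(const Tree &tr, const NumericVector &x,
                         std::vector<double> &phi,
                         int node, std::vector<PathElem> path,
                         double pz, double po, int pi) {
  extend_path(path, pz, po, pi);
  const int f = tr.feat[node];
  if (f < 0) {  // leaf
    const double v = tr.value[node];
    for (size_t i = 1; i < path.size(); ++i) {
      const double w = unwound_sum(path, static_cast<int>(i));
      phi[path[i].d] += w * (path[i].o - path[i].z) * v;
    }
    return;
  }
  // xgboost compares feature value and threshold as float32
  int hot = (static_cast<float>(x[f]) < static_cast<float>(tr.split[node]))
                ? tr.yes[node] : tr.no[node];
  int cold = (hot == tr.yes[node]) ? tr.no[node] : tr.yes[node];
  double iz = 1.0, io = 1.0;
  int k = -1;
  for (size_t i = 1; i < path.size(); ++i)
    if (path[i].d == f) { k = static_cast<int>(i); break; }
  if (k >= 0) {
    iz = path[k].z; io = path[k].o;
    unwind_path(path, k);
  }
  const double cr = tr.cover[node];
  shap_recurse(tr, x, phi, hot, path, iz * tr.cover[hot] / cr, io, f);
  shap_recurse(tr, x, phi, cold, path, iz * tr.cover[cold] / cr, 0.0, f);
}

static double tree_expected(const Tree &tr, int node) {
  if (tr.feat[node] < 0) return tr.value[node];
  const double cr = tr.cover[node];
  return (tr.cover[tr.yes[node]] * tree_expected(tr, tr.yes[node]) +
          tr.cover[tr.no[node]] * tree_expected(tr, tr.no[node])) / cr;
}

static double tree_predict(const Tree &tr, const NumericVector &x) {
  int node = 0;
  while (tr.feat[node] >= 0)
    node = (static_cast<float>(x[tr.feat[node]]) <
            static_cast<float>(tr.split[node])) ? tr.yes[node] : tr.no[node];
  return tr.value[node];
}

// [[Rcpp::export(name = ".treeshap_ensemble")]]
List treeshap_ensemble(List trees, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol(), nt = trees.size();
  std::vector<Tree> ens(nt);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    ens[t].yes = tl["yes"]; ens[t].no = tl["no"]; ens[t].feat = tl["feature"];
    ens[t].split = tl["split"]; ens[t].cover = tl["cover"]; ens[t].value = tl["value"];
  }
  NumericMatrix phi(n, p);
  NumericVector margin(n);
  double bias = 0.0;
  for (int t = 0; t < nt; ++t) bias += tree_expected(ens[t], 0);
  for (int i = 0; i < n; ++i) {
    NumericVector x = X(i, _);
    std::vector<double> acc(p, 0.0);
    double mg = 0.0;
    for (int t = 0; t < nt; ++t) {
      std::vector<PathElem> path;
      path.reserve(32);
      shap_recurse(ens[t], x, acc, 0, path, 1.0, 1.0, -1);
      mg += tree_predict(ens[t], x);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j];
    margin[i] = mg;
  }
  return List::create(_["phi"] = phi, _["bias"] = bias, _["margin"] = margin);
}
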