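#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with path compression; size tracked at roots.
struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  UnionFind(int n) : parent(n, -1), size(n, 0) {}
  void activate(int v) { parent[v] = v; size[v] = 1; }
  bool active(int v) const { return parent[v] >= 0; }
  int find(int v) {
    int r = v;
    while (parent[r] != r) r = parent[r];
    while (parent[v] != r) { int nx = parent[v]; parent[v] = r; v = nx; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

static void neighborOffsets(const IntegerVector& dims, int connectivity,
                            std::vector<int>& offs,
                            std::vector<std::array<int,3> >& doffs) {
  offs.clear(); doffs.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back(dx + dy * dims[0] + dz * dims[0] * dims[1]);
        doffs.push_back({{dx, dy, dz}});
      }
}

// TFCE enhancement of the positive part of a 3-D statistic map.
// Processes thresholds from high to low with an incremental union-find:
// at threshold h every active voxel accumulates extent(h)^E * h^H * dh.
static std::vector<double> tfce_core(const double* x, int V,
                                     const IntegerVector& dims,
                                     double E, double H, double dh,
                                     int connectivity, double hmax,
                                     const std::vector<double>& powE) {
  std::vector<double> out(V, 0.0);
  if (hmax <= 0.0 || dh <= 0.0) return out;
  std::vector<int> order;
  order.reserve(V);
  for (int v = 0; v < V; ++v) if (x[v] > 0) order.push_back(v);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return x[a] > x[b]; });

  std::vector<int> offs;
  std::vector<std::array<int,3> > doffs;
  neighborOffsets(dims, connectivity, offs, doffs);
  int nx = dims[0], ny = dims[1], nxy = dims[0] * dims[1];

  UnionFind uf(V);
  size_t next = 0;
  int nSteps = (int)std::floor(hmax / dh + 1e-9);
  for (int k = nSteps; k >= 1; --k) {
    double h = k * dh;
    // activate voxels with x >= h and connect to active neighbors
    while (next < order.size() && x[order[next]] >= h) {
      int v = order[next++];
      uf.activate(v);
      int vx = v % nx, vy = (v / nx) % ny, vz = v / nxy;
      for (size_t o = 0; o < offs.size(); ++o) {
        int wx = vx + doffs[o][0], wy = vy + doffs[o][1],
            wz = vz + doffs[o][2];
        if (wx < 0 || wx >= nx || wy < 0 || wy >= ny ||
            wz < 0 || wz >= dims[2]) continue;
        int w = v + offs[o];
        if (uf.active(w)) uf.unite(v, w);
      }
    }
    double hH = std::pow(h, H) * dh;
    for (size_t i = 0; i < next; ++i) {
      int v = order[i];
      out[v] += powE[uf.size[uf.find(v)]] * hH;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  int V = x.size();
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) if (x[v] > hmax) hmax = x[v];
  std::vector<double> powE(V + 1);
  for (int s = 0; s <= V; ++s) powE[s] = std::pow((double)s, E);
  std::vector<double> out = tfce_core(REAL(x), V, dims, E, H, dh,
                                      connectivity, hmax, powE);
  return NumericVector(out.begin(), out.end());
}

// One-sample t statistics per column of an n x V matrix with signs s.
static void tcolumns(const double* X, const int* s, int n, int V,
                     std::vector<double>& t) {
  double sqrtn = std::sqrt((double)n);
  for (int v = 0; v < V; ++v) {
    const double* col = X + (size_t)v * n;
    double m = 0.0;
    for (int i = 0; i < n; ++i) m += s[i] * col[i];
    m /= n;
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = s[i] * col[i] - m;
      ss += d * d;
    }
    double sd = std::sqrt(ss / (n - 1));
    t[v] = (sd > 0.0) ? m / (sd / sqrtn) : 0.0;
  }
}

// Sign-permutation null of the max TFCE statistic.
// X: n x V subject maps (column-major, voxels as columns);
// signs: nperm x n matrix of +/-1; nSteps: TFCE integration steps,
// dh = max/nSteps per map. Returns observed t, observed TFCE and the
// per-permutation maxima.
// [[Rcpp::export(name = ".sign_perm_cpp")]]
List sign_perm_cpp(NumericMatrix X, IntegerMatrix signs,
                   IntegerVector dims, double E, double H, int nSteps,
                   int connectivity) {
  int n = X.nrow(), V = X.ncol();
  int nperm = signs.nrow();
  std::vector<double> t(V);
  std::vector<int> s1(n, 1);
  tcolumns(REAL(X), s1.data(), n, V, t);
  std::vector<double> powE(V + 1);
  for (int s = 0; s <= V; ++s) powE[s] = std::pow((double)s, E);
  double hmax = 0.0;
  for (int v = 0; v < V; ++v) if (t[v] > hmax) hmax = t[v];
  std::vector<double> obs = tfce_core(t.data(), V, dims, E, H,
                                      hmax > 0 ? hmax / nSteps : 1.0,
                                      connectivity, hmax, powE);
  NumericVector nullMax(nperm);
  std::vector<int> sp(n);
  std::vector<double> tp(V);
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) sp[i] = signs(p, i);
    tcolumns(REAL(X), sp.data(), n, V, tp);
    double hm = 0.0;
    for (int v = 0; v < V; ++v) if (tp[v] > hm) hm = tp[v];
    if (hm <= 0.0) { nullMax[p] = 0.0; continue; }
    std::vector<double> tf = tfce_core(tp.data(), V, dims, E, H,
                                       hm / nSteps, connectivity, hm, powE);
    nullMax[p] = *std::max_element(tf.begin(), tf.end());
  }
  return List::create(_["t"] = NumericVector(t.begin(), t.end()),
                      _["tfce"] = NumericVector(obs.begin(), obs.end()),
                      _["nullMax"] = nullMax);
}
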