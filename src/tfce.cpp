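#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {
struct UF {
  std::vector<int> parent;
  std::vector<double> extent;
  UF(int n, const std::vector<double> &w) : parent(n, -1), extent(w) {}
  int find(int x) {
    int r = x;
    while (parent[r] >= 0) r = parent[r];
    while (parent[x] >= 0) { int nxt = parent[x]; parent[x] = r; x = nxt; }
    return r;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    parent[b] = a;
    extent[a] += extent[b];
  }
};
} // namespace

// Threshold-free cluster enhancement over an arbitrary adjacency given in
// CSR form (adj_off length n+1, adj_idx 0-based). Enhances the positive
// tail only; extent is the sum of per-node weights (1 for voxels, vertex
// area for meshes). TFCE(v) = sum over thresholds h = dh..h_v of
// e_v(h)^E h^H dh with dh = max(vals)/nsteps.
// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector vals, IntegerVector adj_off,
                       IntegerVector adj_idx, NumericVector extent_w,
                       double E, double H, int nsteps) {
  int n = vals.size();
  NumericVector out(n);
  double vmax = 0;
  for (int i = 0; i < n; ++i) if (vals[i] > vmax) vmax = vals[i];
  if (vmax <= 0) return out;
  double dh = vmax / nsteps;
  // nodes sorted by value descending
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return vals[a] > vals[b]; });
  std::vector<double> w(extent_w.begin(), extent_w.end());
  UF uf(n, w);
  std::vector<char> active(n, 0);
  size_t next = 0;
  // process thresholds from high to low; accumulate into active nodes
  for (int s = nsteps; s >= 1; --s) {
    double h = s * dh;
    while (next < ord.size() && vals[ord[next]] >= h) {
      int v = ord[next++];
      active[v] = 1;
      for (int e = adj_off[v]; e < adj_off[v + 1]; ++e) {
        int u = adj_idx[e];
        if (active[u]) uf.unite(v, u);
      }
    }
    if (next == 0) continue;
    double hH = std::pow(h, H) * dh;
    for (size_t m = 0; m < next; ++m) {
      int v = ord[m];
      out[v] += std::pow(uf.extent[uf.find(v)], E) * hH;
    }
  }
  return out;
}

// CSR adjacency for a 3-D grid with 6/18/26 connectivity.
// [[Rcpp::export]]
List cpp_grid_csr(IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<std::array<int, 3> > offs;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        int ord = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        offs.push_back({di, dj, dk});
      }
  IntegerVector adj_off(n + 1);
  std::vector<int> adj;
  adj.reserve(n * offs.size());
  R_xlen_t q = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++q) {
        adj_off[q] = (int)adj.size();
        for (auto &d : offs) {
          int ii = i + d[0], jj = j + d[1], kk = k + d[2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          adj.push_back(ii + nx * (jj + ny * kk));
        }
      }
  adj_off[n] = (int)adj.size();
  return List::create(_["offsets"] = adj_off,
                      _["neighbours"] = IntegerVector(adj.begin(), adj.end()));
}
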