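#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <utility>
#include <algorithm>
using namespace Rcpp;

// Marching tetrahedra: extracts the zero isosurface of a scalar field
// sampled at voxel centres (level < 0 inside). Each grid cube is split into
// six tetrahedra sharing the main diagonal; crossing vertices are linearly
// interpolated on tetrahedron edges (all of which join two grid nodes) and
// de-duplicated by edge key, so the mesh is watertight wherever the zero set
// is interior to the grid. Triangles are oriented with normals pointing
// towards positive level (outward for a negative interior).
// Returns vertices in continuous 0-based voxel coordinates and 1-based faces.
// [[Rcpp::export]]
List cpp_marching_tetra(NumericVector level, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  auto lin = [&](int i, int j, int k) {
    return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
  };
  // tetrahedral decomposition of the unit cube (corner bit order x,y,z)
  static const int tets[6][4] = {
    {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
    {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  std::vector<double> vx, vy, vz;
  std::vector<int> fa, fb, fc;
  std::unordered_map<uint64_t, int> edge_vert;
  auto edge_vertex = [&](R_xlen_t na, R_xlen_t nb, double la, double lb,
                         const int pa[3], const int pb[3]) -> int {
    uint64_t key = na < nb ? ((uint64_t)na << 32) | (uint64_t)nb
                           : ((uint64_t)nb << 32) | (uint64_t)na;
    auto it = edge_vert.find(key);
    if (it != edge_vert.end()) return it->second;
    double t = la / (la - lb);
    if (!(t >= 0 && t <= 1)) t = 0.5;
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    int id = (int)vx.size() - 1;
    edge_vert[key] = id;
    return id;
  };
  auto emit = [&](int v0, int v1, int v2, const double in_c[3], const double out_c[3]) {
    // orient so the normal points from inside (negative) towards outside
    double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0], az = vz[v1] - vz[v0];
    double bx = vx[v2] - vx[v0], by = vy[v2] - vy[v0], bz = vz[v2] - vz[v0];
    double nxv = ay * bz - az * by, nyv = az * bx - ax * bz, nzv = ax * by - ay * bx;
    double dx = out_c[0] - in_c[0], dy = out_c[1] - in_c[1], dz = out_c[2] - in_c[2];
    if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(v1, v2);
    fa.push_back(v0 + 1); fb.push_back(v1 + 1); fc.push_back(v2 + 1);
  };
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        double lv[8];
        R_xlen_t nid[8];
        int pos[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          pos[c][0] = i + corner[c][0];
          pos[c][1] = j + corner[c][1];
          pos[c][2] = k + corner[c][2];
          nid[c] = lin(pos[c][0], pos[c][1], pos[c][2]);
          lv[c] = level[nid[c]];
          if (lv[c] == 0) lv[c] = 1e-12; // zero counts as outside
          (lv[c] < 0 ? any_in : any_out) = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], dd = tets[t][3];
          int vidx[4] = {a, b, c, dd};
          int inside[4], nin = 0;
          for (int m = 0; m < 4; ++m) inside[m] = lv[vidx[m]] < 0;
          for (int m = 0; m < 4; ++m) nin += inside[m];
          if (nin == 0 || nin == 4) continue;
          // centroids of inside / outside corners for orientation
          double cin[3] = {0, 0, 0}, cout[3] = {0, 0, 0};
          int ci = 0, co = 0;
          for (int m = 0; m < 4; ++m) {
            int v = vidx[m];
            if (inside[m]) {
              for (int ax = 0; ax < 3; ++ax) cin[ax] += pos[v][ax];
              ci++;
            } else {
              for (int ax = 0; ax < 3; ++ax) cout[ax] += pos[v][ax];
              co++;
            }
          }
          for (int ax = 0; ax < 3; ++ax) { cin[ax] /= ci; cout[ax] /= co; }
          // collect crossing-edge vertices
          int ev[4], ne = 0;
          int pairA[4], pairB[4];
          for (int m = 0; m < 4; ++m)
            for (int m2 = m + 1; m2 < 4; ++m2)
              if (inside[m] != inside[m2]) {
                int va = vidx[m], vb = vidx[m2];
                ev[ne] = edge_vertex(nid[va], nid[vb], lv[va], lv[vb],
                                     pos[va], pos[vb]);
                pairA[ne] = m; pairB[ne] = m2;
                ne++;
              }
          if (nin == 1 || nin == 3) {
            // single triangle
            emit(ev[0], ev[1], ev[2], cin, cout);
          } else { // nin == 2: quad; order edges so consecutive ones share a corner
            // edges: each connects one inside and one outside corner. Order as a
            // cycle: e0 shares its inside corner with e1 or e3 etc. Find ordering
            // 0,a,b where e0 and e[a] share a corner.
            int o1 = -1, o2 = -1, o3 = -1;
            for (int m = 1; m < 4; ++m) {
              bool share = (pairA[m] == pairA[0]) || (pairA[m] == pairB[0]) ||
                           (pairB[m] == pairA[0]) || (pairB[m] == pairB[0]);
              if (share && o1 < 0) o1 = m;
              else if (share) o3 = m;
              else o2 = m;
            }
            emit(ev[0], ev[o1], ev[o2], cin, cout);
            emit(ev[0], ev[o2], ev[o3], cin, cout);
          }
        }
      }
  NumericMatrix V(vx.size(), 3);
  for (size_t m = 0; m < vx.size(); ++m) {
    V(m, 0) = vx[m]; V(m, 1) = vy[m]; V(m, 2) = vz[m];
  }
  IntegerMatrix F(fa.size(), 3);
  for (size_t m = 0; m < fa.size(); ++m) {
    F(m, 0) = fa[m]; F(m, 1) = fb[m]; F(m, 2) = fc[m];
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
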