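#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// closest point on triangle (Ericson, Real-Time Collision Detection)
static double tri_dist2(const double p[3], const double a[3], const double b[3],
                        const double c[3]) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  auto dot = [](const double x[3], const double y[3]) {
    return x[0]*y[0] + x[1]*y[1] + x[2]*y[2];
  };
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  double q[3];
  if (d1 <= 0 && d2 <= 0) { for (int i=0;i<3;++i) q[i]=a[i]; goto done; }
  {
    double bp[3]; for (int i=0;i<3;++i) bp[i] = p[i]-b[i];
    double d3 = dot(ab, bp), d4 = dot(ac, bp);
    if (d3 >= 0 && d4 <= d3) { for (int i=0;i<3;++i) q[i]=b[i]; goto done; }
    double vc = d1*d4 - d3*d2;
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      double v = d1 / (d1 - d3);
      for (int i=0;i<3;++i) q[i] = a[i] + v*ab[i];
      goto done;
    }
    double cp[3]; for (int i=0;i<3;++i) cp[i] = p[i]-c[i];
    double d5 = dot(ab, cp), d6 = dot(ac, cp);
    if (d6 >= 0 && d5 <= d6) { for (int i=0;i<3;++i) q[i]=c[i]; goto done; }
    double vb = d5*d2 - d1*d6;
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      double w = d2 / (d2 - d6);
      for (int i=0;i<3;++i) q[i] = a[i] + w*ac[i];
      goto done;
    }
    double va = d3*d6 - d5*d4;
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
      for (int i=0;i<3;++i) q[i] = b[i] + w*(c[i]-b[i]);
      goto done;
    }
    {
      double denom = 1.0 / (va + vb + vc);
      double v = vb * denom, w = vc * denom;
      for (int i=0;i<3;++i) q[i] = a[i] + ab[i]*v + ac[i]*w;
    }
  }
done:
  double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Distance from each query point to a triangle mesh, uniform-grid
// accelerated (exact: expands search shells until the remaining shells
// cannot contain a closer triangle).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dist(NumericMatrix pts, NumericMatrix verts,
                                  IntegerMatrix faces) {
  int nf = faces.nrow(), np = pts.nrow();
  NumericVector out(np);
  if (nf == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  // bbox
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = R_PosInf; hi[ax] = R_NegInf;
    for (int v = 0; v < verts.nrow(); ++v) {
      lo[ax] = std::min(lo[ax], verts(v, ax));
      hi[ax] = std::max(hi[ax], verts(v, ax));
    }
  }
  // cell size: ~2x mean triangle bbox diagonal, bounded for sanity
  double mean_ext = 0;
  for (int f = 0; f < nf; ++f) {
    for (int ax = 0; ax < 3; ++ax) {
      double a = verts(faces(f,0)-1, ax), b = verts(faces(f,1)-1, ax),
             c = verts(faces(f,2)-1, ax);
      mean_ext += std::max({a,b,c}) - std::min({a,b,c});
    }
  }
  mean_ext /= (3.0 * nf);
  double cell = std::max(mean_ext * 2.0, 1e-6);
  int ng[3];
  for (int ax = 0; ax < 3; ++ax) {
    ng[ax] = std::max(1, (int)std::ceil((hi[ax] - lo[ax]) / cell));
    ng[ax] = std::min(ng[ax], 128);
  }
  double cs[3];
  for (int ax = 0; ax < 3; ++ax)
    cs[ax] = std::max((hi[ax] - lo[ax]) / ng[ax], 1e-9);
  auto cidx = [&](int cx, int cy, int cz) {
    return (size_t)cx + (size_t)ng[0] * ((size_t)cy + (size_t)ng[1] * (size_t)cz);
  };
  std::vector<std::vector<int> > bins((size_t)ng[0]*ng[1]*ng[2]);
  for (int f = 0; f < nf; ++f) {
    int clo[3], chi[3];
    for (int ax = 0; ax < 3; ++ax) {
      double a = verts(faces(f,0)-1, ax), b = verts(faces(f,1)-1, ax),
             c = verts(faces(f,2)-1, ax);
      double mn = std::min({a,b,c}), mx = std::max({a,b,c});
      clo[ax] = std::max(0, std::min(ng[ax]-1, (int)((mn - lo[ax]) / cs[ax])));
      chi[ax] = std::max(0, std::min(ng[ax]-1, (int)((mx - lo[ax]) / cs[ax])));
    }
    for (int cz = clo[2]; cz <= chi[2]; ++cz)
      for (int cy = clo[1]; cy <= chi[1]; ++cy)
        for (int cx = clo[0]; cx <= chi[0]; ++cx)
          bins[cidx(cx, cy, cz)].push_back(f);
  }
  double min_cs = std::min({cs[0], cs[1], cs[2]});
  // flat face-corner buffers (Rcpp accessors are too slow for the hot loop)
  std::vector<double> FA(nf * 3), FB(nf * 3), FC(nf * 3);
  for (int f = 0; f < nf; ++f)
    for (int ax = 0; ax < 3; ++ax) {
      FA[f*3+ax] = verts(faces(f,0)-1, ax);
      FB[f*3+ax] = verts(faces(f,1)-1, ax);
      FC[f*3+ax] = verts(faces(f,2)-1, ax);
    }
  std::vector<int> stamp(nf, -1);
  for (int p = 0; p < np; ++p) {
    double pt[3] = {pts(p,0), pts(p,1), pts(p,2)};
    int pc[3];
    for (int ax = 0; ax < 3; ++ax)
      pc[ax] = std::max(0, std::min(ng[ax]-1, (int)((pt[ax]-lo[ax])/cs[ax])));
    double best = R_PosInf;
    int max_r = std::max({ng[0], ng[1], ng[2]});
    auto visit = [&](int cx, int cy, int cz) {
      if (cx < 0 || cx >= ng[0] || cy < 0 || cy >= ng[1] ||
          cz < 0 || cz >= ng[2]) return;
      const std::vector<int> &bf = bins[cidx(cx, cy, cz)];
      for (int f : bf) {
        if (stamp[f] == p) continue;
        stamp[f] = p;
        double d2 = tri_dist2(pt, &FA[f*3], &FB[f*3], &FC[f*3]);
        if (d2 < best) best = d2;
      }
    };
    for (int r = 0; r <= max_r; ++r) {
      if (best < R_PosInf && (double)(r - 1) * min_cs > std::sqrt(best)) break;
      if (r == 0) {
        visit(pc[0], pc[1], pc[2]);
        continue;
      }
      // shell surface only: two full slabs in z, rings elsewhere
      for (int dz = -r; dz <= r; dz += 2 * r)
        for (int dy = -r; dy <= r; ++dy)
          for (int dx = -r; dx <= r; ++dx)
            visit(pc[0] + dx, pc[1] + dy, pc[2] + dz);
      for (int dz = -r + 1; dz <= r - 1; ++dz) {
        for (int dy = -r; dy <= r; dy += 2 * r)
          for (int dx = -r; dx <= r; ++dx)
            visit(pc[0] + dx, pc[1] + dy, pc[2] + dz);
        for (int dx = -r; dx <= r; dx += 2 * r)
          for (int dy = -r + 1; dy <= r - 1; ++dy)
            visit(pc[0] + dx, pc[1] + dy, pc[2] + dz);
      }
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
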