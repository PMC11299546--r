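#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Local surface ratio: for each query vertex, the mesh area inside the
// Euclidean ball of radius r divided by pi r^2. Boundary triangles are
// clipped by recursive 4-way subdivision (depth `depth`, counting
// sub-triangle centroids).
// [[Rcpp::export]]
NumericVector cpp_surface_ratio(NumericMatrix verts, IntegerMatrix faces,
                                IntegerVector query, double radius,
                                int depth = 3) {
  int nf = faces.nrow(), nq = query.size();
  NumericVector out(nq);
  double r2 = radius * radius;
  // precompute face corner coords and areas
  std::vector<double> A(nf * 3), B(nf * 3), C(nf * 3), area(nf);
  for (int f = 0; f < nf; ++f) {
    for (int ax = 0; ax < 3; ++ax) {
      A[f*3+ax] = verts(faces(f,0)-1, ax);
      B[f*3+ax] = verts(faces(f,1)-1, ax);
      C[f*3+ax] = verts(faces(f,2)-1, ax);
    }
    double u[3], v[3], cr[3];
    for (int ax = 0; ax < 3; ++ax) {
      u[ax] = B[f*3+ax] - A[f*3+ax];
      v[ax] = C[f*3+ax] - A[f*3+ax];
    }
    cr[0] = u[1]*v[2]-u[2]*v[1]; cr[1] = u[2]*v[0]-u[0]*v[2];
    cr[2] = u[0]*v[1]-u[1]*v[0];
    area[f] = 0.5 * std::sqrt(cr[0]*cr[0]+cr[1]*cr[1]+cr[2]*cr[2]);
  }
  // recursive clipped-area fraction of a triangle vs ball(center, r)
  std::function<double(const double*, const double*, const double*,
                       const double*, int)> frac =
    [&](const double *a, const double *b, const double *c,
        const double *ctr, int lev) -> double {
      auto d2 = [&](const double *p) {
        double dx = p[0]-ctr[0], dy = p[1]-ctr[1], dz = p[2]-ctr[2];
        return dx*dx + dy*dy + dz*dz;
      };
      bool ia = d2(a) <= r2, ib = d2(b) <= r2, ic = d2(c) <= r2;
      if (ia && ib && ic) return 1.0;
      if (lev == 0) {
        double m[3] = {(a[0]+b[0]+c[0])/3, (a[1]+b[1]+c[1])/3,
                       (a[2]+b[2]+c[2])/3};
        return d2(m) <= r2 ? 1.0 : 0.0;
      }
      if (!ia && !ib && !ic) {
        // fully outside if even the closest corner is far beyond r + diameter
        double dmin = std::min({d2(a), d2(b), d2(c)});
        double e2 = 0;
        for (int ax = 0; ax < 3; ++ax) {
          double dab = a[ax]-b[ax], dacv = a[ax]-c[ax];
          e2 += dab*dab + dacv*dacv;
        }
        if (std::sqrt(dmin) > radius + std::sqrt(e2)) return 0.0;
      }
      double ab[3], bc[3], ca[3];
      for (int ax = 0; ax < 3; ++ax) {
        ab[ax] = (a[ax]+b[ax])/2; bc[ax] = (b[ax]+c[ax])/2;
        ca[ax] = (c[ax]+a[ax])/2;
      }
      return 0.25 * (frac(a, ab, ca, ctr, lev-1) + frac(ab, b, bc, ctr, lev-1) +
                     frac(ca, bc, c, ctr, lev-1) + frac(ab, bc, ca, ctr, lev-1));
    };
  for (int q = 0; q < nq; ++q) {
    int vi = query[q] - 1;
    double ctr[3] = {verts(vi,0), verts(vi,1), verts(vi,2)};
    double acc = 0;
    for (int f = 0; f < nf; ++f) {
      // provable reject: corner a farther than r plus the triangle extent
      const double *a = &A[f*3], *b = &B[f*3], *c = &C[f*3];
      double dx = a[0]-ctr[0], dy = a[1]-ctr[1], dz = a[2]-ctr[2];
      double da = dx*dx+dy*dy+dz*dz;
      double e = 0;
      for (int ax = 0; ax < 3; ++ax) {
        double d1 = a[ax]-b[ax], d2v = a[ax]-c[ax];
        e += d1*d1 + d2v*d2v;
      }
      if (std::sqrt(da) > radius + std::sqrt(e)) continue;
      acc += area[f] * frac(a, b, c, ctr, depth);
    }
    out[q] = acc / (M_PI * r2);
  }
  return out;
}
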