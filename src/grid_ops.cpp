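#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Index helpers: arrays are column-major [i,j,k], i fastest, 0-based.
static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Separable Gaussian convolution, zero-padded borders (plain convolution,
// no renormalisation). sigma given in voxel units per axis; sigma <= 0 skips
// that axis.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector arr, IntegerVector dim,
                                  NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> out(buf.size());
  int n[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(4.0 * s);
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &w : ker) w /= sum;
    // stride along the axis
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c[3] = {i, j, k};
          double acc = 0.0;
          for (int t = -r; t <= r; ++t) {
            int cc = c[ax] + t;
            if (cc < 0 || cc >= n[ax]) continue;
            int idx[3] = {i, j, k};
            idx[ax] = cc;
            acc += ker[t + r] * buf[lin(idx[0], idx[1], idx[2], nx, ny)];
          }
          out[lin(i, j, k, nx, ny)] = acc;
        }
    buf.swap(out);
  }
  NumericVector res(buf.begin(), buf.end());
  return res;
}

// Sliding-window box mean with window half-width `radius`, border-truncated
// (mean over in-grid window voxels). Separable.
// [[Rcpp::export]]
NumericVector cpp_box_mean(NumericVector arr, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> buf(arr.begin(), arr.end());
  std::vector<double> cnt(buf.size(), 1.0);
  std::vector<double> out(buf.size()), ocnt(buf.size());
  int n[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int c[3] = {i, j, k};
          double acc = 0.0, ac = 0.0;
          for (int t = -radius; t <= radius; ++t) {
            int cc = c[ax] + t;
            if (cc < 0 || cc >= n[ax]) continue;
            int idx[3] = {i, j, k};
            idx[ax] = cc;
            acc += buf[lin(idx[0], idx[1], idx[2], nx, ny)];
            ac += cnt[lin(idx[0], idx[1], idx[2], nx, ny)];
          }
          out[lin(i, j, k, nx, ny)] = acc;
          ocnt[lin(i, j, k, nx, ny)] = ac;
        }
    buf.swap(out);
    cnt.swap(ocnt);
  }
  NumericVector res(buf.size());
  for (R_xlen_t q = 0; q < (R_xlen_t)buf.size(); ++q)
    res[q] = cnt[q] > 0 ? buf[q] / cnt[q] : 0.0;
  return res;
}

// Trilinear sampling at continuous 0-based voxel coordinates (N x 3).
// Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector arr, IntegerVector dim,
                            NumericMatrix coords, double fill = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = coords.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (!(x >= 0 && x <= nx - 1 && y >= 0 && y <= ny - 1 && z >= 0 && z <= nz - 1)) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double c000 = arr[lin(i0, j0, k0, nx, ny)], c100 = arr[lin(i1, j0, k0, nx, ny)];
    double c010 = arr[lin(i0, j1, k0, nx, ny)], c110 = arr[lin(i1, j1, k0, nx, ny)];
    double c001 = arr[lin(i0, j0, k1, nx, ny)], c101 = arr[lin(i1, j0, k1, nx, ny)];
    double c011 = arr[lin(i0, j1, k1, nx, ny)], c111 = arr[lin(i1, j1, k1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx;
    double c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx;
    double c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Nearest-neighbour sampling (for label volumes).
// [[Rcpp::export]]
NumericVector cpp_nearest(NumericVector arr, IntegerVector dim,
                          NumericMatrix coords, double fill = 0.0) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t np = coords.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; ++p) {
    int i = (int)std::lround(coords(p, 0));
    int j = (int)std::lround(coords(p, 1));
    int k = (int)std::lround(coords(p, 2));
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz)
      out[p] = fill;
    else
      out[p] = arr[lin(i, j, k, nx, ny)];
  }
  return out;
}

// Counts of each label value among the 6-neighbours of every voxel
// (labels 1..nclass; 0 = outside/ignored). Returns N x nclass matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_potts_counts(IntegerVector labels, IntegerVector dim,
                               int nclass) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerMatrix out(n, nclass);
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t q = lin(i, j, k, nx, ny);
        for (int t = 0; t < 6; ++t) {
          int ii = i + d[t][0], jj = j + d[t][1], kk = k + d[t][2];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
            continue;
          int lb = labels[lin(ii, jj, kk, nx, ny)];
          if (lb >= 1 && lb <= nclass) out(q, lb - 1)++;
        }
      }
  return out;
}
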