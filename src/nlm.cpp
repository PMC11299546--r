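#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline R_xlen_t lin3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Spatially adaptive non-local means: patch radius `patch_r` (3^3 patches by
// default), search radius `search_r` (7^3), Gaussian patch weights
// exp(-||dP||^2 / (2 beta sigma_local^2 npatch)). sigma_local = 0 voxels are
// passed through unchanged. Patches are compared with border clamping.
// [[Rcpp::export]]
NumericVector cpp_sanlm(NumericVector arr, IntegerVector dim,
                        NumericVector sigma_local, double beta = 1.0,
                        int patch_r = 1, int search_r = 3) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(arr.size());
  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };
  int npatch = (2 * patch_r + 1) * (2 * patch_r + 1) * (2 * patch_r + 1);
  for (int k = 0; k < nz; ++k) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t q = lin3(i, j, k, nx, ny);
        double sig = sigma_local[q];
        if (!(sig > 0)) { out[q] = arr[q]; continue; }
        double h2 = 2.0 * beta * sig * sig * npatch;
        double wsum = 0.0, acc = 0.0;
        for (int dk = -search_r; dk <= search_r; ++dk)
          for (int dj = -search_r; dj <= search_r; ++dj)
            for (int di = -search_r; di <= search_r; ++di) {
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
                continue;
              double dist2 = 0.0;
              for (int pk = -patch_r; pk <= patch_r; ++pk)
                for (int pj = -patch_r; pj <= patch_r; ++pj)
                  for (int pi = -patch_r; pi <= patch_r; ++pi) {
                    double a = arr[lin3(clampi(i + pi, 0, nx - 1),
                                        clampi(j + pj, 0, ny - 1),
                                        clampi(k + pk, 0, nz - 1), nx, ny)];
                    double b = arr[lin3(clampi(ii + pi, 0, nx - 1),
                                        clampi(jj + pj, 0, ny - 1),
                                        clampi(kk + pk, 0, nz - 1), nx, ny)];
                    dist2 += (a - b) * (a - b);
                  }
              double w = std::exp(-dist2 / h2);
              wsum += w;
              acc += w * arr[lin3(ii, jj, kk, nx, ny)];
            }
        out[q] = acc / wsum;
      }
  }
  return out;
}
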