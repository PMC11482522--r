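#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 1-D squared Euclidean distance transform (lower envelope of parabolas),
// sample spacing w. Infinite inputs (no source on this line yet) are skipped
// when building the envelope. f is overwritten with the result.
static void dt1d(std::vector<double> &f, int n, double w,
                 std::vector<double> &d, std::vector<int> &v,
                 std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) {
        --k;
        if (k < 0) break;
      } else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) return;  // whole line unreachable
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[j + 1] < xq) ++j;
    double dx = xq - v[j] * w;
    d[q] = dx * dx + f[v[j]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance (mm) from each foreground voxel centre to the nearest
// background voxel centre; 0 on background; Inf if the grid holds no
// background. Out-of-grid voxels are not treated as background.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> D(n);
  for (R_xlen_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // x-axis
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) line[i] = D[base + i];
      dt1d(line, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = line[i];
    }
  // y-axis
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) line[j] = D[base + (R_xlen_t)j * nx];
      dt1d(line, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = line[j];
    }
  // z-axis
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) line[k] = D[base + (R_xlen_t)k * nx * ny];
      dt1d(line, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * nx * ny] = line[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(D[i]);
  return out;
}
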