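#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
}

// neighbour offsets: 6 = faces only, 26 = full 3x3x3 shell
static void offsets(int connectivity, std::vector<int> &di,
                    std::vector<int> &dj, std::vector<int> &dk) {
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Connected component of `candidate` containing `seed` (1-based linear index).
// [[Rcpp::export]]
LogicalVector flood_from_seed_cpp(LogicalVector candidate, IntegerVector dims,
                                  double seed_linear, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::vector<int> di, dj, dk;
  offsets(connectivity, di, dj, dk);
  std::queue<R_xlen_t> q;
  R_xlen_t s = (R_xlen_t)seed_linear - 1;
  if (!candidate[s]) return out;
  out[s] = TRUE;
  q.push(s);
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    int rem = (int)(cur % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (size_t m = 0; m < di.size(); ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t idx = lin(ii, jj, kk, nx, ny);
      if (candidate[idx] && !out[idx]) {
        out[idx] = TRUE;
        q.push(idx);
      }
    }
  }
  return out;
}

// Label all connected components of a binary mask (labels 1..k, 0 background).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> di, dj, dk;
  offsets(connectivity, di, dj, dk);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      int rem = (int)(cur % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      for (size_t m = 0; m < di.size(); ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        R_xlen_t idx = lin(ii, jj, kk, nx, ny);
        if (mask[idx] && !lab[idx]) {
          lab[idx] = next;
          q.push(idx);
        }
      }
    }
  }
  return lab;
}

// Fill fully enclosed background cavities: background is tracked with
// 6-connectivity from the grid border; anything not reached becomes mask.
// [[Rcpp::export]]
LogicalVector fill_holes_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(n, 0);
  std::vector<int> di, dj, dk;
  offsets(6, di, dj, dk);
  std::queue<R_xlen_t> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        R_xlen_t idx = lin(i, j, k, nx, ny);
        if (!mask[idx] && !outside[idx]) {
          outside[idx] = 1;
          q.push(idx);
        }
      }
  while (!q.empty()) {
    R_xlen_t cur = q.front(); q.pop();
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    int rem = (int)(cur % ((R_xlen_t)nx * ny));
    int j = rem / nx, i = rem % nx;
    for (size_t m = 0; m < di.size(); ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
        continue;
      R_xlen_t idx = lin(ii, jj, kk, nx, ny);
      if (!mask[idx] && !outside[idx]) {
        outside[idx] = 1;
        q.push(idx);
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}
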