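#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

// Homotopic thinning with the standard (26, 6) digital-topology pairing:
// a border voxel may be deleted when it is a simple point (deletion preserves
// both object and background topology) and not a curve endpoint. Deletion
// proceeds in increasing distance-transform order so the surviving curve
// stays medial. Voxels outside the grid count as background.

// ---- static 3x3x3 neighbourhood topology -------------------------------
// cell index = a + 3*b + 9*c, a,b,c in {0,1,2}; centre = 13.

static std::vector<std::vector<int> > adj26;  // 26-adjacency within cube, no centre
static std::vector<std::vector<int> > adj6;   // 6-adjacency within N18 cells
static std::vector<int> n18cells;             // cells in the 18-neighbourhood
static std::vector<int> facecells;            // the 6 face neighbours
static bool topo_ready = false;

static void build_topology() {
  if (topo_ready) return;
  adj26.assign(27, std::vector<int>());
  adj6.assign(27, std::vector<int>());
  for (int p = 0; p < 27; ++p) {
    if (p == 13) continue;
    int pa = p % 3, pb = (p / 3) % 3, pc = p / 9;
    int nd = (pa != 1) + (pb != 1) + (pc != 1);
    if (nd == 1) facecells.push_back(p);
    if (nd == 1 || nd == 2) n18cells.push_back(p);
    for (int q = 0; q < 27; ++q) {
      if (q == 13 || q == p) continue;
      int qa = q % 3, qb = (q / 3) % 3, qc = q / 9;
      int da = std::abs(pa - qa), db = std::abs(pb - qb), dc = std::abs(pc - qc);
      if (da <= 1 && db <= 1 && dc <= 1) adj26[p].push_back(q);
      if (da + db + dc == 1) adj6[p].push_back(q);
    }
  }
  topo_ready = true;
}

// nb[27]: object occupancy of the 3x3x3 neighbourhood (centre included).
static bool is_simple(const bool nb[27]) {
  // (1) exactly one 26-component of object voxels among the 26 neighbours
  bool seen[27];
  std::memset(seen, 0, sizeof(seen));
  int comp_obj = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == 13 || !nb[p] || seen[p]) continue;
    if (++comp_obj > 1) return false;
    std::queue<int> q;
    q.push(p); seen[p] = true;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      for (size_t m = 0; m < adj26[cur].size(); ++m) {
        int nxt = adj26[cur][m];
        if (nxt != 13 && nb[nxt] && !seen[nxt]) { seen[nxt] = true; q.push(nxt); }
      }
    }
  }
  if (comp_obj != 1) return false;

  // (2) exactly one 6-component of background in the 18-neighbourhood that
  //     touches a face neighbour of the centre
  std::memset(seen, 0, sizeof(seen));
  int comp_bg = 0;
  for (size_t fi = 0; fi < facecells.size(); ++fi) {
    int f = facecells[fi];
    if (nb[f] || seen[f]) continue;
    if (++comp_bg > 1) return false;
    std::queue<int> q;
    q.push(f); seen[f] = true;
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      for (size_t m = 0; m < adj6[cur].size(); ++m) {
        int nxt = adj6[cur][m];
        // restrict walk to the 18-neighbourhood (6-adjacent cells of an N18
        // cell are either N18 cells or the centre/corners; exclude those)
        int na = nxt % 3, nbq = (nxt / 3) % 3, nc = nxt / 9;
        int nd = (na != 1) + (nbq != 1) + (nc != 1);
        if (nxt == 13 || nd == 3 || nd == 0) continue;
        if (!nb[nxt] && !seen[nxt]) { seen[nxt] = true; q.push(nxt); }
      }
    }
  }
  return comp_bg == 1;
}

// [[Rcpp::export]]
LogicalVector thin_skeleton_cpp(LogicalVector mask, IntegerVector dims,
                                NumericVector dist) {
  build_topology();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> obj(n);
  for (R_xlen_t i = 0; i < n; ++i) obj[i] = mask[i] ? 1 : 0;

  std::vector<R_xlen_t> cand;
  cand.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    // border voxels (some 6-neighbour is background or out of grid)
    cand.clear();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          R_xlen_t idx = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
          if (!obj[idx]) continue;
          bool border =
            i == 0 || i == nx - 1 || j == 0 || j == ny - 1 || k == 0 ||
            k == nz - 1 || !obj[idx - 1] || !obj[idx + 1] ||
            !obj[idx - nx] || !obj[idx + nx] ||
            !obj[idx - (R_xlen_t)nx * ny] || !obj[idx + (R_xlen_t)nx * ny];
          if (border) cand.push_back(idx);
        }
    std::stable_sort(cand.begin(), cand.end(),
                     [&](R_xlen_t a, R_xlen_t b) { return dist[a] < dist[b]; });
    for (size_t c = 0; c < cand.size(); ++c) {
      R_xlen_t idx = cand[c];
      if (!obj[idx]) continue;
      int k = (int)(idx / ((R_xlen_t)nx * ny));
      int rem = (int)(idx % ((R_xlen_t)nx * ny));
      int j = rem / nx, i = rem % nx;
      bool nb[27];
      int nobj = 0;
      for (int dc = -1; dc <= 1; ++dc)
        for (int db = -1; db <= 1; ++db)
          for (int da = -1; da <= 1; ++da) {
            int ii = i + da, jj = j + db, kk = k + dc;
            int cell = (da + 1) + 3 * (db + 1) + 9 * (dc + 1);
            bool in = ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny &&
                      kk < nz;
            nb[cell] =
              in && obj[(R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii];
            if (cell != 13 && nb[cell]) ++nobj;
          }
      if (nobj <= 1) continue;  // curve endpoint (or isolated): keep
      if (is_simple(nb)) {
        obj[idx] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = obj[i] != 0;
  return out;
}
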