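// Connected components, boundary extraction and point-set distances for
// the evaluation metrics. Connectivity is 6, 18 or 26 (3D).
#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

static inline long id3(int x, int y, int z, int nx, int ny, int nz) {
  return x + (long)nx * (y + (long)ny * z);
}

static std::vector<std::array<int,3>> neigh_offsets(int connectivity) {
  std::vector<std::array<int,3>> off;
  for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
      int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
      if (m == 0) continue;
      if (connectivity == 6 && m > 1) continue;
      if (connectivity == 18 && m > 2) continue;
      off.push_back({dx, dy, dz});
    }
  return off;
}

// Label connected components of a binary mask; labels are 1..ncomp in
// scan-discovery order. Returns an integer array.
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  IntegerVector lab(nvox);
  lab.attr("dim") = dims;
  auto off = neigh_offsets(connectivity);
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(lab);
  int cur = 0;
  std::queue<long> q;
  for (long s = 0; s < nvox; ++s) {
    if (!mp[s] || lp[s]) continue;
    ++cur;
    lp[s] = cur;
    q.push(s);
    while (!q.empty()) {
      long v = q.front(); q.pop();
      int x = v % nx, y = (v / nx) % ny, z = v / ((long)nx * ny);
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        long w = id3(xx, yy, zz, nx, ny, nz);
        if (mp[w] && !lp[w]) { lp[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

// Boundary voxels: foreground with at least one background neighbour under
// the connectivity; the outside of the grid counts as background.
// [[Rcpp::export(name = ".boundary_mask")]]
LogicalVector boundary_mask(LogicalVector mask, IntegerVector dims,
                            int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nvox = (long)nx * ny * nz;
  LogicalVector out(nvox);
  out.attr("dim") = dims;
  auto off = neigh_offsets(connectivity);
  const int* mp = LOGICAL(mask);
  int* op = LOGICAL(out);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      long v = id3(x, y, z, nx, ny, nz);
      if (!mp[v]) { op[v] = FALSE; continue; }
      bool bnd = false;
      for (auto& o : off) {
        int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz ||
            !mp[id3(xx, yy, zz, nx, ny, nz)]) { bnd = true; break; }
      }
      op[v] = bnd;
    }
  return out;
}

// For each row of A (n x 3, mm coordinates), the distance to the nearest
// row of B. Brute force; boundary point sets are small.
// [[Rcpp::export(name = ".min_dists")]]
NumericVector min_dists(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    double ax = A(i,0), ay = A(i,1), az = A(i,2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - B(j,0), dy = ay - B(j,1), dz = az - B(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
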