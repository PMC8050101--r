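// 3D morphological thinning of a binary volume to a curve skeleton.
//
// Iterative directional border thinning: a foreground voxel is deletable when
// it is simple (removal preserves topology) and not a curve endpoint. The
// simple-point test is the classical characterization on the 3x3x3
// neighborhood: exactly one 26-connected foreground component among the 26
// neighbors, and exactly one 6-connected background component within the
// 18-neighborhood that touches a face neighbor. Deletion is sequential with
// re-checking, in raster order within six directional subiterations, so the
// result is deterministic and the centerline stays medial.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// local 3x3x3 neighborhood indexed by (dz+1) + 3*(dy+1) + 9*(dx+1)
static inline int loc(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

static bool simple_point(const bool nb[27]) {
  // C*: 26-components of foreground among the 26 neighbors
  bool seen[27] = {false};
  int comp_fg = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comp_fg++;
    if (comp_fg > 1) return false;
    // BFS over the 26-neighborhood cells (center excluded)
    std::vector<int> stack(1, i);
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3, cy = (c / 3) % 3, cx = c / 9;
      for (int dx = -1; dx <= 1; dx++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dz = -1; dz <= 1; dz++) {
            int nx = cx + dx, ny = cy + dy, nz = cz + dz;
            if (nx < 0 || nx > 2 || ny < 0 || ny > 2 || nz < 0 || nz > 2)
              continue;
            int m = nz + 3 * ny + 9 * nx;
            if (m == 13 || m == c || seen[m] || !nb[m]) continue;
            seen[m] = true;
            stack.push_back(m);
          }
    }
  }
  if (comp_fg != 1) return false;

  // C-bar: 6-components of background within N18, touching a face neighbor.
  // N18 = cells with |dx|+|dy|+|dz| <= 2 (excluding center).
  bool seenb[27] = {false};
  int comp_bg = 0;
  static const int face[6] = {loc(-1, 0, 0), loc(1, 0, 0), loc(0, -1, 0),
                              loc(0, 1, 0),  loc(0, 0, -1), loc(0, 0, 1)};
  for (int fi = 0; fi < 6; fi++) {
    int i = face[fi];
    if (nb[i] || seenb[i]) continue;
    comp_bg++;
    if (comp_bg > 1) return false;
    std::vector<int> stack(1, i);
    seenb[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
      static const int d6[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                                   {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
      for (int k = 0; k < 6; k++) {
        int nx = cx + d6[k][0], ny = cy + d6[k][1], nz = cz + d6[k][2];
        if (nx < -1 || nx > 1 || ny < -1 || ny > 1 || nz < -1 || nz > 1)
          continue;
        if (std::abs(nx) + std::abs(ny) + std::abs(nz) > 2) continue;  // N18 only
        int m = loc(nz, ny, nx);
        if (m == 13 || nb[m] || seenb[m]) continue;
        seenb[m] = true;
        stack.push_back(m);
      }
    }
  }
  return comp_bg == 1;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector vol, IntegerVector dims) {
  int nz = dims[0], ny = dims[1], nx = dims[2];
  size_t N = (size_t)nz * ny * nx;
  std::vector<char> v(N);
  for (size_t i = 0; i < N; i++) v[i] = vol[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> char {
    if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) return 0;
    return v[(size_t)z + (size_t)nz * (y + (size_t)ny * x)];
  };
  auto fill_nb = [&](int z, int y, int x, bool nb[27]) {
    for (int dx = -1; dx <= 1; dx++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dz = -1; dz <= 1; dz++)
          nb[loc(dz, dy, dx)] = at(z + dz, y + dy, x + dx) != 0;
  };
  auto n_fg_neighbors = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; i++)
      if (i != 13 && nb[i]) c++;
    return c;
  };

  static const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                                 {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int xx = 0; xx < nx; xx++)
        for (int yy = 0; yy < ny; yy++)
          for (int zz = 0; zz < nz; zz++) {
            size_t i = (size_t)zz + (size_t)nz * (yy + (size_t)ny * xx);
            if (!v[i]) continue;
            if (at(zz + dirs[d][0], yy + dirs[d][1], xx + dirs[d][2]) != 0)
              continue;  // not a border voxel in this direction
            cand.push_back(i);
          }
      for (size_t q = 0; q < cand.size(); q++) {
        size_t i = cand[q];
        if (!v[i]) continue;
        int zz = (int)(i % nz);
        int yy = (int)((i / nz) % ny);
        int xx = (int)(i / ((size_t)nz * ny));
        bool nb[27];
        fill_nb(zz, yy, xx, nb);
        int nn = n_fg_neighbors(nb);
        if (nn <= 1) continue;  // endpoint or isolated: keep
        if (!simple_point(nb)) continue;
        v[i] = 0;
        changed = true;
      }
    }
  }

  LogicalVector out(vol.size());
  for (size_t i = 0; i < N; i++) out[i] = v[i] != 0;
  out.attr("dim") = dims;
  return out;
}
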