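#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The 13 unique 3D direction vectors at Chebyshev distance 1 (one per
// antipodal pair); the opposite directions are implied by symmetrization.
static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, -1, 1}, {1, 1, -1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

static inline bool inb(int x, int y, int z, int nx, int ny, int nz) {
  return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
}

// Gray-level co-occurrence counts over the 13 directions at distance 1,
// symmetrized (each ordered pair counted both ways) and merged across
// directions before any normalization. `levels` holds 0 outside the mask.
// [[Rcpp::export]]
NumericMatrix glcm_counts_cpp(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericMatrix M(G, G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        for (int d = 0; d < NDIR; ++d) {
          const int xx = x + DIRS[d][0], yy = y + DIRS[d][1], zz = z + DIRS[d][2];
          if (!inb(xx, yy, zz, nx, ny, nz)) continue;
          const int lj = levels[idx3(xx, yy, zz, nx, ny)];
          if (lj <= 0) continue;
          M(li - 1, lj - 1) += 1.0;
          M(lj - 1, li - 1) += 1.0;
        }
      }
  return M;
}

// Run-length counts: maximal same-level runs per direction, summed over the
// 13 directions (each voxel belongs to exactly one run per direction).
// [[Rcpp::export]]
NumericMatrix glrlm_counts_cpp(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int rmax = std::max(nx, std::max(ny, nz));
  NumericMatrix M(G, rmax);
  for (int d = 0; d < NDIR; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int li = levels[idx3(x, y, z, nx, ny)];
          if (li <= 0) continue;
          // run starts where the previous voxel along d is absent or differs
          const int px = x - dx, py = y - dy, pz = z - dz;
          if (inb(px, py, pz, nx, ny, nz) &&
              levels[idx3(px, py, pz, nx, ny)] == li)
            continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (inb(cx, cy, cz, nx, ny, nz) &&
                 levels[idx3(cx, cy, cz, nx, ny)] == li) {
            ++len;
            cx += dx; cy += dy; cz += dz;
          }
          M(li - 1, len - 1) += 1.0;
        }
  }
  return M;
}

// 26-connected same-level zones; returns a two-column matrix (level, size).
// [[Rcpp::export]]
IntegerMatrix glszm_zones_cpp(IntegerVector levels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        const int i0 = idx3(x0, y0, z0, nx, ny);
        const int li = levels[i0];
        if (li <= 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          const int i = stack.back();
          stack.pop_back();
          ++size;
          const int x = i % nx, y = (i / nx) % ny, zc = i / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                const int xx = x + dx, yy = y + dy, zz = zc + dz;
                if (!inb(xx, yy, zz, nx, ny, nz)) continue;
                const int j = idx3(xx, yy, zz, nx, ny);
                if (!seen[j] && levels[j] == li) {
                  seen[j] = 1;
                  stack.push_back(j);
                }
              }
        }
        zl.push_back(li);
        zs.push_back(size);
      }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) {
    out(k, 0) = zl[k];
    out(k, 1) = zs[k];
  }
  return out;
}

// NGTDM table: per level, number of counted voxels n_i and the accumulated
// absolute difference s_i between the voxel level and the mean level of its
// in-mask 26-neighborhood (out-of-mask neighbors excluded from the mean).
// [[Rcpp::export]]
List ngtdm_table_cpp(IntegerVector levels, IntegerVector dims, int G) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ni(G), si(G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int li = levels[idx3(x, y, z, nx, ny)];
        if (li <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              if (!inb(xx, yy, zz, nx, ny, nz)) continue;
              const int lj = levels[idx3(xx, yy, zz, nx, ny)];
              if (lj > 0) {
                sum += lj;
                ++cnt;
              }
            }
        if (cnt > 0) {
          ni[li - 1] += 1.0;
          si[li - 1] += std::fabs(li - sum / cnt);
        }
      }
  return List::create(_["n"] = ni, _["s"] = si);
}
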