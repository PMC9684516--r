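#include <Rcpp.h>
using namespace Rcpp;

// Resample a 3D grid to isotropic `target` spacing. The grid origin is the
// volume corner; voxel centers sit at (i + 0.5) * spacing. The output grid
// shares the input origin and its extent is round(extent / target) voxels.
// mode 0 = trilinear (intensities), mode 1 = nearest neighbor (masks).
// [[Rcpp::export]]
NumericVector resample_grid_cpp(NumericVector values, IntegerVector dims,
                                NumericVector spacing, IntegerVector odims,
                                double target, int mode) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = odims[0], oy = odims[1], oz = odims[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  R_xlen_t k = 0;
  for (int z = 0; z < oz; ++z) {
    const double cz = ((z + 0.5) * target) / sz - 0.5;
    for (int y = 0; y < oy; ++y) {
      const double cy = ((y + 0.5) * target) / sy - 0.5;
      for (int x = 0; x < ox; ++x, ++k) {
        const double cx = ((x + 0.5) * target) / sx - 0.5;
        if (mode == 1) {
          int ix = (int)std::lround(cx), iy = (int)std::lround(cy),
              iz = (int)std::lround(cz);
          ix = std::min(std::max(ix, 0), nx - 1);
          iy = std::min(std::max(iy, 0), ny - 1);
          iz = std::min(std::max(iz, 0), nz - 1);
          out[k] = values[ix + nx * (iy + (R_xlen_t)ny * iz)];
        } else {
          double fx = std::min(std::max(cx, 0.0), (double)(nx - 1));
          double fy = std::min(std::max(cy, 0.0), (double)(ny - 1));
          double fz = std::min(std::max(cz, 0.0), (double)(nz - 1));
          const int x0 = std::min((int)fx, nx - 2 >= 0 ? nx - 2 : 0);
          const int y0 = std::min((int)fy, ny - 2 >= 0 ? ny - 2 : 0);
          const int z0 = std::min((int)fz, nz - 2 >= 0 ? nz - 2 : 0);
          const int x1 = std::min(x0 + 1, nx - 1);
          const int y1 = std::min(y0 + 1, ny - 1);
          const int z1 = std::min(z0 + 1, nz - 1);
          const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
          double acc = 0.0;
          const double wx[2] = {1.0 - tx, tx};
          const double wy[2] = {1.0 - ty, ty};
          const double wz[2] = {1.0 - tz, tz};
          const int xs[2] = {x0, x1}, ys[2] = {y0, y1}, zs[2] = {z0, z1};
          for (int c = 0; c < 2; ++c)
            for (int b = 0; b < 2; ++b)
              for (int a = 0; a < 2; ++a)
                acc += wx[a] * wy[b] * wz[c] *
                       values[xs[a] + nx * (ys[b] + (R_xlen_t)ny * zs[c])];
          out[k] = acc;
        }
      }
    }
  }
  return out;
}
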