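#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of a 3D array at fractional voxel coordinates.
// coords are 1-based voxel coordinates (column per axis); points whose
// 8-voxel support is not fully inside the array return `fill`.
// [[Rcpp::export(name = ".cpp_trilinear_gather")]]
NumericVector cpp_trilinear_gather(NumericVector arr, IntegerVector dim,
                                   NumericMatrix coords, double fill = 0.0) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  NumericVector out(n);
  const double *a = REAL(arr);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0) - 1.0, y = coords(p, 1) - 1.0, z = coords(p, 2) - 1.0;
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix < 0 || iy < 0 || iz < 0 || ix > nx - 2 || iy > ny - 2 || iz > nz - 2) {
      out[p] = fill;
      continue;
    }
    double fx = x - ix, fy = y - iy, fz = z - iz;
    R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
    R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double c000 = a[base],            c100 = a[base + sx];
    double c010 = a[base + sy],       c110 = a[base + sx + sy];
    double c001 = a[base + sz],       c101 = a[base + sx + sz];
    double c011 = a[base + sy + sz],  c111 = a[base + sx + sy + sz];
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

// Adjoint of the gather: distribute each value (and its unit weight) onto the
// 8 voxels surrounding its fractional coordinate, accumulating into `num`
// and `wt` (modified in place; both length prod(dim)). Points outside the
// support are skipped and counted in the return value.
// [[Rcpp::export(name = ".cpp_trilinear_scatter")]]
int cpp_trilinear_scatter(NumericVector num, NumericVector wt,
                          IntegerVector dim, NumericMatrix coords,
                          NumericVector vals, NumericVector pointwt) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = coords.nrow();
  const bool haspw = pointwt.size() == n;
  double *pn = REAL(num), *pw = REAL(wt);
  int dropped = 0;
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = coords(p, 0) - 1.0, y = coords(p, 1) - 1.0, z = coords(p, 2) - 1.0;
    int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
    if (ix < 0 || iy < 0 || iz < 0 || ix > nx - 2 || iy > ny - 2 || iz > nz - 2) {
      ++dropped;
      continue;
    }
    double fx = x - ix, fy = y - iy, fz = z - iz;
    double v = vals[p];
    double w0 = haspw ? pointwt[p] : 1.0;
    R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
    R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
    double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    for (int kz = 0; kz < 2; ++kz)
      for (int ky = 0; ky < 2; ++ky)
        for (int kx = 0; kx < 2; ++kx) {
          double w = w0 * wx[kx] * wy[ky] * wz[kz];
          R_xlen_t at = base + kx * sx + ky * sy + kz * sz;
          pn[at] += w * v;
          pw[at] += w;
        }
  }
  return dropped;
}

// Gaussian bump accumulation: add, for each peak (center, height, sigma in
// voxel units), height * exp(-r^2 / (2 sigma^2)) / ((2 pi)^{3/2} sigma^3)
// over voxels within `cut` sigmas, clipped to the array.
// [[Rcpp::export(name = ".cpp_add_gaussians")]]
void cpp_add_gaussians(NumericVector arr, IntegerVector dim,
                       NumericMatrix centers, NumericVector heights,
                       double sigma, double cut) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double *a = REAL(arr);
  const double norm = 1.0 / (std::pow(2.0 * M_PI, 1.5) * sigma * sigma * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r = cut * sigma, r2 = r * r;
  for (R_xlen_t p = 0; p < centers.nrow(); ++p) {
    double cx = centers(p, 0) - 1.0, cy = centers(p, 1) - 1.0, cz = centers(p, 2) - 1.0;
    double h = heights[p] * norm;
    int x0 = std::max(0, (int)std::ceil(cx - r)), x1 = std::min(nx - 1, (int)std::floor(cx + r));
    int y0 = std::max(0, (int)std::ceil(cy - r)), y1 = std::min(ny - 1, (int)std::floor(cy + r));
    int z0 = std::max(0, (int)std::ceil(cz - r)), z1 = std::min(nz - 1, (int)std::floor(cz + r));
    for (int z = z0; z <= z1; ++z) {
      double dz2 = (z - cz) * (z - cz);
      for (int y = y0; y <= y1; ++y) {
        double dyz2 = dz2 + (y - cy) * (y - cy);
        if (dyz2 > r2) continue;
        R_xlen_t row = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = x0; x <= x1; ++x) {
          double d2 = dyz2 + (x - cx) * (x - cx);
          if (d2 <= r2) a[row + x] += h * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
}
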