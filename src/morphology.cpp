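#include <Rcpp.h>
using namespace Rcpp;

// Grayscale erosion (erode = true) or dilation over an explicit set of
// integer voxel offsets on a 3D array stored column-major as (z, y, x).
// Out-of-volume neighbours are ignored (equivalent to +Inf padding for
// erosion, -Inf for dilation).
// [[Rcpp::export]]
NumericVector morph_gray_cpp(NumericVector arr, IntegerVector dims,
                             IntegerMatrix offsets, bool erode) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double init = erode ? R_PosInf : R_NegInf;
  NumericVector out((R_xlen_t)nz * ny * nx, init);
  const int K = offsets.nrow();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  for (int k = 0; k < K; ++k) {
    const int dz = offsets(k, 0), dy = offsets(k, 1), dx = offsets(k, 2);
    const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
    const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
    const int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
    const R_xlen_t doff = dz + (R_xlen_t)dy * sy + (R_xlen_t)dx * sx;
    for (int x = x0; x < x1; ++x) {
      for (int y = y0; y < y1; ++y) {
        R_xlen_t base = (R_xlen_t)x * sx + (R_xlen_t)y * sy;
        for (int z = z0; z < z1; ++z) {
          const R_xlen_t i = base + z;
          const double v = arr[i + doff];
          if (erode) {
            if (v < out[i]) out[i] = v;
          } else {
            if (v > out[i]) out[i] = v;
          }
        }
      }
    }
  }
  return out;
}
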