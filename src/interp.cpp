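#include <Rcpp.h>
using namespace Rcpp;

// Trilinear interpolation of an nchan-channel volume at continuous 0-based
// index coordinates. Channels are on the fastest axis of `vals`
// (layout: nchan x nx x ny x nz). Points outside the domain return the
// background value.
// [[Rcpp::export]]
NumericMatrix cpp_trilinear(NumericVector vals, IntegerVector dims, int nchan,
                            NumericMatrix idx, NumericVector background) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = idx.nrow();
  NumericMatrix out(n, nchan);
  const double *v = REAL(vals);
  for (int p = 0; p < n; ++p) {
    double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0 && y >= 0 && z >= 0 && x <= nx - 1 && y <= ny - 1 && z <= nz - 1)) {
      for (int c = 0; c < nchan; ++c) out(p, c) = background[c % background.size()];
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1) i0--;
    if (j0 == ny - 1) j0--;
    if (k0 == nz - 1) k0--;
    if (nx == 1) i0 = 0;
    if (ny == 1) j0 = 0;
    if (nz == 1) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    if (nx == 1) fx = 0;
    if (ny == 1) fy = 0;
    if (nz == 1) fz = 0;
    for (int c = 0; c < nchan; ++c) {
      double acc = 0.0;
      for (int dk = 0; dk < 2; ++dk) {
        int k = k0 + (nz == 1 ? 0 : dk);
        double wz = dk ? fz : 1 - fz;
        if (nz == 1 && dk) continue;
        for (int dj = 0; dj < 2; ++dj) {
          int j = j0 + (ny == 1 ? 0 : dj);
          double wy = dj ? fy : 1 - fy;
          if (ny == 1 && dj) continue;
          for (int di = 0; di < 2; ++di) {
            int i = i0 + (nx == 1 ? 0 : di);
            double wx = di ? fx : 1 - fx;
            if (nx == 1 && di) continue;
            size_t off = ((size_t)k * ny + j) * nx + i;
            acc += wx * wy * wz * v[off * nchan + c];
          }
        }
      }
      out(p, c) = acc;
    }
  }
  return out;
}
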