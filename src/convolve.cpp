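#include <Rcpp.h>
using namespace Rcpp;

// Fold an out-of-range index back into [0, n) by symmetric reflection
// (scipy-style "reflect": d c b a | a b c d | d c b a). Iterated so kernels
// wider than the axis still resolve.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// 1D convolution of a 3D column-major array along one axis (0 = x fastest,
// 1 = y, 2 = z) with a centred odd-length kernel, reflected boundaries.
// [[Rcpp::export(name = ".convAxis")]]
NumericVector conv_axis(const NumericVector& vol, const IntegerVector& dims,
                        const NumericVector& kernel, const int axis) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  if (vol.size() != ntot) stop("volume length does not match dims");
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int kr = klen / 2;

  NumericVector out(no_init(ntot));
  const double* v = vol.begin();
  const double* k = kernel.begin();
  double* o = out.begin();

  const int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1
                        : (axis == 1) ? (R_xlen_t)nx
                        : (R_xlen_t)nx * ny;
  // number of independent lines and how to enumerate them
  std::vector<double> line(n + 2 * kr);

  const int nlines_a = (axis == 0) ? ny : nx;
  const int nlines_b = (axis == 2) ? ny : nz;
  const R_xlen_t step_a = (axis == 0) ? (R_xlen_t)nx : 1;
  const R_xlen_t step_b = (axis == 2) ? (R_xlen_t)nx : (R_xlen_t)nx * ny;

  for (int b = 0; b < nlines_b; ++b) {
    for (int a = 0; a < nlines_a; ++a) {
      const R_xlen_t base = (R_xlen_t)a * step_a + (R_xlen_t)b * step_b;
      // gather the padded line once: cache-friendly inner loop below
      for (int i = -kr; i < n + kr; ++i)
        line[i + kr] = v[base + (R_xlen_t)reflect_index(i, n) * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        const double* lp = &line[i];
        for (int j = 0; j < klen; ++j) acc += lp[j] * k[klen - 1 - j];
        o[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}
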