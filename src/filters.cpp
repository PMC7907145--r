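#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-form II transposed biquad cascade, forward-backward, with
// odd-reflection edge padding and step steady-state initial conditions.
// sos: nsec x 6 (b0 b1 b2 a0 a1 a2), a0 == 1.

namespace {

void sosfilt_inplace(const NumericMatrix &sos, std::vector<double> &x,
                     const std::vector<double> &zi_unit, double x0) {
  const int nsec = sos.nrow();
  const int n = (int)x.size();
  for (int s = 0; s < nsec; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = zi_unit[2 * s] * x0, z2 = zi_unit[2 * s + 1] * x0;
    for (int i = 0; i < n; ++i) {
      const double xi = x[i];
      const double y = b0 * xi + z1;
      z1 = b1 * xi - a1 * y + z2;
      z2 = b2 * xi - a2 * y;
      x[i] = y;
    }
  }
}

// per-section steady state for a unit step input, with cascaded DC scaling
std::vector<double> step_zi(const NumericMatrix &sos) {
  const int nsec = sos.nrow();
  std::vector<double> zi(2 * nsec);
  double scale = 1.0;
  for (int s = 0; s < nsec; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    const double h1 = (b0 + b1 + b2) / (1.0 + a1 + a2);
    zi[2 * s] = scale * (h1 - b0);
    zi[2 * s + 1] = scale * (b2 - a2 * h1);
    scale *= h1;
  }
  return zi;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix sosfiltfilt_mat_cpp(NumericMatrix x, NumericMatrix sos, int padlen) {
  const int nr = x.nrow(), nc = x.ncol();
  if (padlen >= nc) stop("padlen must be < signal length");
  NumericMatrix out(nr, nc);
  std::vector<double> zi = step_zi(sos);
  std::vector<double> ext(nc + 2 * padlen);
  for (int r = 0; r < nr; ++r) {
    // odd reflection about both end points
    for (int i = 0; i < padlen; ++i)
      ext[i] = 2.0 * x(r, 0) - x(r, padlen - i);
    for (int i = 0; i < nc; ++i) ext[padlen + i] = x(r, i);
    for (int i = 0; i < padlen; ++i)
      ext[padlen + nc + i] = 2.0 * x(r, nc - 1) - x(r, nc - 2 - i);
    sosfilt_inplace(sos, ext, zi, ext[0]);
    std::reverse(ext.begin(), ext.end());
    sosfilt_inplace(sos, ext, zi, ext[0]);
    std::reverse(ext.begin(), ext.end());
    for (int i = 0; i < nc; ++i) out(r, i) = ext[padlen + i];
  }
  return out;
}
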