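#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squared Pearson correlation between a two-band index and a trait, for
// every ordered band pair. X is samples x bands (column-major), y the
// trait. type: 0 = RSI (R1/R2), 1 = NDSI ((R1-R2)/(R1+R2)).
// RSI is not symmetric in (i, j) (the reciprocal is a nonlinear transform),
// so the full square is computed; the NDSI map is symmetric (negation
// preserves R^2) and only the lower triangle is computed then mirrored.
// Cells with a near-zero denominator in any sample, or a constant index,
// are set to NA. Rows/cols follow the column order of X (lambda1 = row).
// [[Rcpp::export]]
NumericMatrix pair_r2_scan_cpp(NumericMatrix X, NumericVector y, int type) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(p, p);
  std::fill(out.begin(), out.end(), NA_REAL);

  double ybar = 0.0;
  for (int k = 0; k < n; ++k) ybar += y[k];
  ybar /= n;
  std::vector<double> yc(n);
  double syy = 0.0;
  for (int k = 0; k < n; ++k) { yc[k] = y[k] - ybar; syy += yc[k] * yc[k]; }
  if (syy <= 0.0) return out;

  const double eps = 1e-12;
  const bool sym = (type == 1);

  for (int i = 0; i < p; ++i) {
    const double *xi = &X(0, i);
    const int jmax = sym ? i : p;
    for (int j = 0; j < jmax; ++j) {
      if (j == i) continue;
      const double *xj = &X(0, j);
      double sz = 0.0, szz = 0.0, szy = 0.0;
      bool bad = false;
      for (int k = 0; k < n; ++k) {
        double den, z;
        if (type == 0) {
          den = xj[k];
          if (std::fabs(den) < eps) { bad = true; break; }
          z = xi[k] / den;
        } else {
          den = xi[k] + xj[k];
          if (std::fabs(den) < eps) { bad = true; break; }
          z = (xi[k] - xj[k]) / den;
        }
        sz += z; szz += z * z; szy += z * yc[k];
      }
      if (bad) continue;
      double vz = szz - sz * sz / n;
      if (vz <= eps * (szz > 0 ? szz : 1.0)) continue;  // constant index
      double r2 = (szy * szy) / (vz * syy);
      if (r2 > 1.0) r2 = 1.0;
      out(i, j) = r2;
      if (sym) out(j, i) = r2;
    }
  }
  return out;
}
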