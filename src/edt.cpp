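#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Cells with no seed carry BIG instead of +Inf so the envelope arithmetic
// stays finite. A parabola rooted at a BIG cell can never undercut one rooted
// at a genuine seed as long as the true squared distances stay below BIG/2,
// which holds for any grid up to ~1e4 pixels per side.
static const double BIG = 1e9;
static const double ZINF = 1e30;

// Exact 1-D squared distance transform of a sampled function
// (Felzenszwalb & Huttenlocher lower-envelope algorithm).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -ZINF;
  z[1] = ZINF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = ZINF;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    while (z[j + 1] < q) j++;
    double dq = (double)(q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix seed) {
  int nr = seed.nrow(), nc = seed.ncol();
  NumericMatrix out(nr, nc);

  std::vector<double> f(nr), d(nr);
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++)
      f[i] = (seed(i, j) == TRUE) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  std::vector<double> fr(nc), dr(nc);
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) fr[j] = out(i, j);
    dt1d(fr, dr, nc);
    for (int j = 0; j < nc; j++) out(i, j) = dr[j];
  }
  // cells unreachable from any seed come back at BIG scale; mark them NA
  for (int i = 0; i < nr * nc; i++)
    if (out[i] >= BIG / 2) out[i] = NA_REAL;
  return out;
}
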