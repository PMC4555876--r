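// Grid kernels: exact Euclidean distance transform (Felzenszwalb &
// Huttenlocher two-pass lower envelope) and nearest-neighbour NoData fill
// ("nibble") with a deterministic row-major tie-break.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();
// finite 'no site' sentinel: a true infinity makes the envelope
// intersection -inf and underflows k (Felzenszwalb's reference code uses
// 1e20 for the same reason)
const double BIG = 1e15;

// 1-D squared distance transform of sampled function f, result into d
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

}  // namespace

// squared distance (in cell units) to the nearest cell where feature != 0
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericMatrix edt_sq_cpp(IntegerMatrix feature) {
  const int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix d(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // columns pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = (feature(i, j) != 0) ? 0.0 : BIG;
    dt1d(f, dd, nr, v, z);
    for (int i = 0; i < nr; ++i) d(i, j) = dd[i];
  }
  // rows pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, dd, nc, v, z);
    for (int j = 0; j < nc; ++j) d(i, j) = dd[j];
  }
  return d;
}

// Fill NA cells lying inside `inmask` with the value of the nearest non-NA
// cell (Euclidean centre-to-centre distance). Equidistant donors resolve to
// the earliest cell in row-major scan order. Ring search: the minimum
// Euclidean distance attainable in the Chebyshev ring at radius r is r, so
// the search stops once r exceeds the best distance found.
// [[Rcpp::export(name = ".nibble_cpp")]]
NumericMatrix nibble_cpp(NumericMatrix vals, LogicalMatrix inmask) {
  const int nr = vals.nrow(), nc = vals.ncol();
  bool any_valid = false;
  for (int i = 0; i < nr * nc && !any_valid; ++i)
    if (!NumericVector::is_na(vals[i])) any_valid = true;
  if (!any_valid) stop("grid is entirely NoData: nothing to nibble from");

  NumericMatrix out = clone(vals);
  int rmax = std::max(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!inmask(i, j) || !NumericVector::is_na(vals(i, j))) continue;
      double best_d2 = INF;
      long best_lin = -1;
      double best_val = NA_REAL;
      for (int r = 1; r <= rmax; ++r) {
        if ((double)(r - 1) * (r - 1) > best_d2) break;
        int i0 = i - r, i1 = i + r, j0 = j - r, j1 = j + r;
        for (int ii = std::max(i0, 0); ii <= std::min(i1, nr - 1); ++ii) {
          bool edge_row = (ii == i0 || ii == i1);
          int jstep = edge_row ? 1 : (j1 - j0);
          if (jstep <= 0) jstep = 1;
          for (int jj = j0; jj <= j1; jj += jstep) {
            if (jj < 0 || jj >= nc) continue;
            if (NumericVector::is_na(vals(ii, jj))) continue;
            double di = ii - i, dj = jj - j;
            double d2 = di * di + dj * dj;
            long lin = (long)ii * nc + jj;  // row-major scan order
            if (d2 < best_d2 - 1e-12 ||
                (std::abs(d2 - best_d2) <= 1e-12 && lin < best_lin)) {
              best_d2 = d2;
              best_lin = lin;
              best_val = vals(ii, jj);
            }
          }
        }
      }
      out(i, j) = best_val;
    }
  }
  return out;
}
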