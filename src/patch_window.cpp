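#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Quantile with linear interpolation between order statistics (R's type 7),
// computed on an already-sorted vector.
static double q_type7_sorted(const std::vector<double>& x, double p) {
  const int n = (int)x.size();
  if (n == 1) return x[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return x[n - 1];
  double g = h - lo;
  return x[lo] + g * (x[lo + 1] - x[lo]);
}

// Sliding rectangular-window median and IQR of a height grid.
// h: ny x nx matrix (rows along the track, columns across it).
// hy, hx: window half-extents in nodes; windows are clipped at the grid
// edges, matching the clipped-patch convention of patch_stats().
// [[Rcpp::export]]
List patch_window_stats_cpp(NumericMatrix h, int hy, int hx) {
  const int ny = h.nrow(), nx = h.ncol();
  NumericMatrix iqr(ny, nx), med(ny, nx);
  std::vector<double> buf;
  buf.reserve((size_t)(2 * hy + 1) * (2 * hx + 1));
  for (int j = 0; j < nx; ++j) {
    const int j0 = std::max(0, j - hx), j1 = std::min(nx - 1, j + hx);
    for (int i = 0; i < ny; ++i) {
      const int i0 = std::max(0, i - hy), i1 = std::min(ny - 1, i + hy);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj) {
        const double* col = &h(0, jj);
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(col[ii]);
      }
      std::sort(buf.begin(), buf.end());
      med(i, j) = q_type7_sorted(buf, 0.5);
      iqr(i, j) = q_type7_sorted(buf, 0.75) - q_type7_sorted(buf, 0.25);
    }
  }
  return List::create(_["median"] = med, _["iqr"] = iqr);
}
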