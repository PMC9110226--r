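#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// median of 2..4 values: with an even count, the mean of the two middle values
static inline double small_median(double* v, int n) {
  std::sort(v, v + n);
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

static inline int gather_neighbors(const NumericMatrix& p, int i, int j,
                                   int nr, int nc, double* buf) {
  int n = 0;
  if (i > 0)      buf[n++] = p(i - 1, j);
  if (i < nr - 1) buf[n++] = p(i + 1, j);
  if (j > 0)      buf[n++] = p(i, j - 1);
  if (j < nc - 1) buf[n++] = p(i, j + 1);
  return n;
}

// Four-neighborhood median at every grid position; the neighborhood shrinks
// at edges (3 values) and corners (2 values). A 1x1 grid returns its own value.
// [[Rcpp::export]]
NumericMatrix cpp_neighbor_median(const NumericMatrix& p) {
  int nr = p.nrow(), nc = p.ncol();
  NumericMatrix out(nr, nc);
  double buf[4];
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int n = gather_neighbors(p, i, j, nr, nc, buf);
      out(i, j) = n > 0 ? small_median(buf, n) : p(i, j);
    }
  }
  return out;
}

// One Gauss-Seidel sweep of p_i <- (y_i + beta*var_i*median(N_i)) / (1 + beta*var_i),
// visiting rays in raster order (row-major: along a view, then next view) or its
// reverse; previously visited rays contribute their already-updated values.
// `p` must be a fresh copy owned by the caller; it is updated in place.
// Returns the updated matrix and the maximum absolute update of the sweep.
// [[Rcpp::export]]
List cpp_gs_sweep(NumericMatrix p, const NumericMatrix& y,
                  const NumericMatrix& v, double beta, bool reverse) {
  int nr = p.nrow(), nc = p.ncol();
  int total = nr * nc;
  double delta = 0.0;
  double buf[4];
  for (int t = 0; t < total; ++t) {
    int idx = reverse ? total - 1 - t : t;
    int i = idx / nc, j = idx % nc;
    int n = gather_neighbors(p, i, j, nr, nc, buf);
    double med = n > 0 ? small_median(buf, n) : p(i, j);
    double bs = beta * v(i, j);
    double pn = (y(i, j) + bs * med) / (1.0 + bs);
    double d = std::fabs(pn - p(i, j));
    if (d > delta) delta = d;
    p(i, j) = pn;
  }
  return List::create(_["p"] = p, _["delta"] = delta);
}

// Pixel-driven parallel-beam forward projection. Pixel (row, col) sits at
// x = col - (n-1)/2 (rightward), y = (n-1)/2 - row (upward), in pixel units.
// Its value is deposited with linear weights into the two detector bins
// bracketing s = x cos(theta) + y sin(theta); bins are spaced one pixel apart
// and centred on the rotation axis. The operator is the exact transpose of
// cpp_back_project.
// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img,
                                  const NumericVector& angles_rad, int n_bins) {
  int n = img.nrow();
  int na = angles_rad.size();
  NumericMatrix sino(na, n_bins);
  double c0 = (n - 1) / 2.0, s0 = (n_bins - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double co = std::cos(angles_rad[a]);
    double si = std::sin(angles_rad[a]);
    for (int col = 0; col < n; ++col) {
      double x = col - c0;
      for (int row = 0; row < n; ++row) {
        double val = img(row, col);
        if (val == 0.0) continue;
        double yy = c0 - row;
        double b = x * co + yy * si + s0;
        int k0 = (int)std::floor(b);
        double w = b - k0;
        if (k0 >= 0 && k0 < n_bins)         sino(a, k0)     += (1.0 - w) * val;
        if (k0 + 1 >= 0 && k0 + 1 < n_bins) sino(a, k0 + 1) += w * val;
      }
    }
  }
  return sino;
}

// Linear-interpolation back-projection onto an n x n grid (unfiltered;
// filtering is done by the caller). Exact transpose of cpp_forward_project.
// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& sino,
                               const NumericVector& angles_rad, int n) {
  int na = sino.nrow(), nb = sino.ncol();
  NumericMatrix img(n, n);
  double c0 = (n - 1) / 2.0, s0 = (nb - 1) / 2.0;
  for (int a = 0; a < na; ++a) {
    double co = std::cos(angles_rad[a]);
    double si = std::sin(angles_rad[a]);
    for (int col = 0; col < n; ++col) {
      double x = col - c0;
      for (int row = 0; row < n; ++row) {
        double yy = c0 - row;
        double b = x * co + yy * si + s0;
        int k0 = (int)std::floor(b);
        double w = b - k0;
        double val = 0.0;
        if (k0 >= 0 && k0 < nb)         val += (1.0 - w) * sino(a, k0);
        if (k0 + 1 >= 0 && k0 + 1 < nb) val += w * sino(a, k0 + 1);
        img(row, col) += val;
      }
    }
  }
  return img;
}
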