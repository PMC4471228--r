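#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Closed-form least squares for grey = plateau + beta1 * min(x - psi, 0)
// at a fixed breakpoint psi. With u_i = min(x_i - psi, 0) this is simple
// regression of y on u with intercept; the plateau side contributes u = 0.
static void fitAtPsi(const double* x, const double* y, int n, double psi,
                     double& beta1, double& plateau, double& sse) {
  double su = 0, suu = 0, sy = 0, suy = 0, syy = 0;
  for (int i = 0; i < n; ++i) {
    double u = x[i] - psi;
    if (u > 0) u = 0;
    su += u; suu += u * u;
    sy += y[i]; suy += u * y[i]; syy += y[i] * y[i];
  }
  double sxx = suu - su * su / n;
  double sxy = suy - su * sy / n;
  double syc = syy - sy * sy / n;
  if (sxx <= 0) {           // no points left of psi: flat line only
    beta1 = 0.0;
    plateau = sy / n;
    sse = syc;
    return;
  }
  beta1 = sxy / sxx;
  plateau = (sy - beta1 * su) / n;
  sse = syc - beta1 * sxy;
  if (sse < 0) sse = 0;     // guard tiny negative round-off
}

static double sseAt(const double* x, const double* y, int n, double psi) {
  double b1, pl, sse;
  fitAtPsi(x, y, n, psi, b1, pl, sse);
  return sse;
}

// Golden-section minimisation of the SSE profile on [a, b].
static double golden(const double* x, const double* y, int n,
                     double a, double b, double tol) {
  const double gr = 0.6180339887498949;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = sseAt(x, y, n, c), fd = sseAt(x, y, n, d);
  while (b - a > tol) {
    if (fc <= fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = sseAt(x, y, n, c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = sseAt(x, y, n, d);
    }
  }
  return (a + b) / 2;
}

// Refine within a bracket: dense sub-scan guards against multiple local
// minima inside the bracket, then golden section polishes.
static double refine(const double* x, const double* y, int n,
                     double a, double b, double tol) {
  const int m = 41;
  double best = a, fbest = sseAt(x, y, n, a);
  for (int i = 1; i < m; ++i) {
    double p = a + (b - a) * i / (m - 1.0);
    double f = sseAt(x, y, n, p);
    if (f < fbest) { fbest = f; best = p; }
  }
  double step = (b - a) / (m - 1.0);
  double lo = std::max(a, best - step), hi = std::min(b, best + step);
  double psi = golden(x, y, n, lo, hi, tol);
  // tie-break: keep the dense-scan point if golden did not improve
  if (sseAt(x, y, n, psi) > fbest) psi = best;
  return psi;
}

struct FitResult {
  double psi, beta1, plateau, sse;
  bool boundary;
};

static FitResult profileFit(const double* x, const double* y, int n,
                            double lo, double hi, int ngrid,
                            double psi0, double tol) {
  FitResult r;
  int best = 0;
  double fbest = R_PosInf;
  std::vector<double> grid(ngrid);
  for (int i = 0; i < ngrid; ++i)
    grid[i] = lo + (hi - lo) * i / (ngrid - 1.0);
  if (R_finite(psi0) && psi0 > lo && psi0 < hi) {
    // seed the scan at the requested start value
    grid.push_back(psi0);
    std::sort(grid.begin(), grid.end());
  }
  int g = (int)grid.size();
  for (int i = 0; i < g; ++i) {
    double f = sseAt(x, y, n, grid[i]);
    if (f < fbest) { fbest = f; best = i; }  // strict: smallest psi on ties
  }
  double a = grid[std::max(0, best - 1)];
  double b = grid[std::min(g - 1, best + 1)];
  r.psi = refine(x, y, n, a, b, tol);
  fitAtPsi(x, y, n, r.psi, r.beta1, r.plateau, r.sse);
  r.boundary = (best == 0 || best == g - 1);
  return r;
}

// [[Rcpp::export(name = ".cppPlateauProfile")]]
List cppPlateauProfile(NumericVector x, NumericVector y, NumericVector grid) {
  int n = x.size(), m = grid.size();
  NumericVector sse(m), beta1(m), plateau(m);
  for (int i = 0; i < m; ++i)
    fitAtPsi(x.begin(), y.begin(), n, grid[i], beta1[i], plateau[i], sse[i]);
  return List::create(_["psi"] = grid, _["sse"] = sse,
                      _["beta1"] = beta1, _["plateau"] = plateau);
}

// [[Rcpp::export(name = ".cppPlateauFit")]]
List cppPlateauFit(NumericVector x, NumericVector y, double lo, double hi,
                   int ngrid, double psi0, double tol) {
  FitResult r = profileFit(x.begin(), y.begin(), x.size(), lo, hi,
                           ngrid, psi0, tol);
  return List::create(_["psi"] = r.psi, _["beta1"] = r.beta1,
                      _["plateau"] = r.plateau, _["sse"] = r.sse,
                      _["boundary"] = r.boundary);
}

// Case-resampling bootstrap refits. idx is 1-based (n x B) as produced by
// sample.int in R, so the RNG stream stays under R's control.
// [[Rcpp::export(name = ".cppPlateauBoot")]]
NumericMatrix cppPlateauBoot(NumericVector x, NumericVector y,
                             IntegerMatrix idx, int ngrid, double tol) {
  int n = idx.nrow(), B = idx.ncol();
  NumericMatrix out(B, 2);
  std::vector<double> xb(n), yb(n), xs(n);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < n; ++i) {
      int k = idx(i, b) - 1;
      xb[i] = x[k]; yb[i] = y[k];
    }
    xs = xb;
    std::sort(xs.begin(), xs.end());
    double eps = 1e-9 * (xs[n - 1] - xs[0] + 1.0);
    double lo = xs[1] + eps, hi = xs[n - 2] - eps;
    if (!(lo < hi)) { out(b, 0) = NA_REAL; out(b, 1) = 0; continue; }
    FitResult r = profileFit(&xb[0], &yb[0], n, lo, hi, ngrid,
                             NA_REAL, tol);
    int nl = 0, nr = 0;
    for (int i = 0; i < n; ++i) {
      if (xb[i] < r.psi) ++nl; else if (xb[i] > r.psi) ++nr;
    }
    out(b, 0) = r.psi;
    out(b, 1) = (!r.boundary && nl >= 2 && nr >= 2) ? 1 : 0;
  }
  return out;
}
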