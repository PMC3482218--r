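// Deterministic accessible-surface engine.
//
// Unit-sphere test points come from a fixed golden-section spiral, so results
// are exactly reproducible for a given n_points (no RNG anywhere).  Each test
// point on the expanded sphere (r_i + probe) is accessible when it lies
// outside every neighbour's expanded sphere; ASA_i = 4*pi*(r_i+probe)^2 *
// accessible fraction.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<double> spiral_points(int n) {
  // returns 3*n doubles (x,y,z interleaved) on the unit sphere
  std::vector<double> p(3 * (size_t)n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int k = 0; k < n; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n;
    double rho = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * k;
    p[3 * (size_t)k]     = rho * std::cos(phi);
    p[3 * (size_t)k + 1] = rho * std::sin(phi);
    p[3 * (size_t)k + 2] = z;
  }
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points, IntegerVector targets) {
  const int n = coords.nrow();
  if (radii.size() != n) stop("radii length mismatch");
  if (n_points < 60) stop("n_points must be >= 60");
  if (probe < 0) stop("probe must be >= 0");
  std::vector<double> pts = spiral_points(n_points);
  NumericVector out(targets.size());

  const double* X = REAL(coords);          // column-major: X[i], X[i+n], X[i+2n]
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int t = 0; t < targets.size(); ++t) {
    int i = targets[t] - 1;
    if (i < 0 || i >= n) stop("target index out of range");
    double xi = X[i], yi = X[i + n], zi = X[i + 2 * n], ri = er[i];

    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X[j] - xi, dy = X[j + n] - yi, dz = X[j + 2 * n] - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rs = ri + er[j];
      if (d2 < rs * rs) {
        if (d2 < 1e-12)
          stop("coincident atom centers (indices %d and %d)", i + 1, j + 1);
        nbr.push_back(j);
      }
    }

    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double px = xi + ri * pts[3 * (size_t)k];
      double py = yi + ri * pts[3 * (size_t)k + 1];
      double pz = zi + ri * pts[3 * (size_t)k + 2];
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = px - X[j], dy = py - X[j + n], dz = pz - X[j + 2 * n];
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { free_pt = false; break; }
      }
      if (free_pt) ++acc;
    }
    out[t] = 4.0 * M_PI * ri * ri * (double)acc / n_points;
  }
  return out;
}

// Accessible surface dots pushed radially to (r_i + offset) from each atom
// center; used to generate solvent pseudo-sites for Voronoi capping.
// [[Rcpp::export]]
NumericMatrix cpp_surface_dots(NumericMatrix coords, NumericVector radii,
                               double probe, int n_points, double offset) {
  const int n = coords.nrow();
  if (n_points < 12) stop("n_points must be >= 12");
  std::vector<double> pts = spiral_points(n_points);
  const double* X = REAL(coords);
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<double> dots;
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    double xi = X[i], yi = X[i + n], zi = X[i + 2 * n], ri = er[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = X[j] - xi, dy = X[j + n] - yi, dz = X[j + 2 * n] - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double rs = ri + er[j];
      if (d2 < rs * rs) nbr.push_back(j);
    }
    double push = radii[i] + offset;
    for (int k = 0; k < n_points; ++k) {
      double ux = pts[3 * (size_t)k], uy = pts[3 * (size_t)k + 1],
             uz = pts[3 * (size_t)k + 2];
      double px = xi + ri * ux, py = yi + ri * uy, pz = zi + ri * uz;
      bool free_pt = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        int j = nbr[m];
        double dx = px - X[j], dy = py - X[j + n], dz = pz - X[j + 2 * n];
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) { free_pt = false; break; }
      }
      if (free_pt) {
        dots.push_back(xi + push * ux);
        dots.push_back(yi + push * uy);
        dots.push_back(zi + push * uz);
      }
    }
  }
  int m = (int)(dots.size() / 3);
  NumericMatrix out(m, 3);
  for (int k = 0; k < m; ++k) {
    out(k, 0) = dots[3 * (size_t)k];
    out(k, 1) = dots[3 * (size_t)k + 1];
    out(k, 2) = dots[3 * (size_t)k + 2];
  }
  return out;
}
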