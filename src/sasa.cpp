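#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
// Test points are placed on each solvent-expanded sphere with a
// deterministic Fibonacci lattice; a point is accessible if it lies
// outside every other atom's expanded sphere.  Neighbour lists use a
// simple O(n^2) cutoff, adequate for the structure sizes handled here.

// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix xyz, NumericVector radii,
                                 double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // Fibonacci sphere points (unit sphere)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double zi = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - zi * zi));
    double th = golden * i;
    px[i] = r * std::cos(th);
    py[i] = r * std::sin(th);
    pz[i] = zi;
  }

  std::vector<double> ax(n), ay(n), az(n), er(n);
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) {
    ax[i] = xyz(i, 0); ay[i] = xyz(i, 1); az[i] = xyz(i, 2);
    er[i] = radii[i] + probe;
    if (er[i] > rmax) rmax = er[i];
  }

  // contiguous neighbour buffers for the hot loop
  std::vector<double> nx, ny, nz, nr2;
  nx.reserve(128); ny.reserve(128); nz.reserve(128); nr2.reserve(128);

  for (int i = 0; i < n; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i], ri = er[i];
    nx.clear(); ny.clear(); nz.clear(); nr2.clear();
    const double cut = ri + rmax;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = ax[j] - xi, dy = ay[j] - yi, dz = az[j] - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      double lim = ri + er[j];
      if (d2 < cut * cut && d2 < lim * lim) {
        nx.push_back(ax[j]); ny.push_back(ay[j]); nz.push_back(az[j]);
        nr2.push_back(er[j] * er[j]);
      }
    }
    const int m = (int)nx.size();
    int acc = 0;
    int last = 0;  // spatially coherent points often share a blocker
    for (int p = 0; p < n_points; ++p) {
      const double qx = xi + ri * px[p];
      const double qy = yi + ri * py[p];
      const double qz = zi + ri * pz[p];
      bool free_pt = true;
      for (int kk = 0; kk < m; ++kk) {
        int k = kk == 0 ? last : (kk == last ? 0 : kk);
        double dx = qx - nx[k], dy = qy - ny[k], dz = qz - nz[k];
        if (dx * dx + dy * dy + dz * dz < nr2[k]) {
          free_pt = false;
          last = k;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return out;
}
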