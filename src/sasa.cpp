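#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley accessible surface area with a deterministic golden-spiral
// sphere quadrature.  `radii` are already probe-expanded (r_vdw + r_probe).
// Returns the exposed area per atom in A^2.
// [[Rcpp::export]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii, int n_points) {
  const int n = coords.nrow();
  if (n_points < 100) stop("n_points must be >= 100");

  // golden-spiral points on the unit sphere (deterministic)
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    const double ri = radii[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - xi, dy = coords(j, 1) - yi,
                   dz = coords(j, 2) - zi;
      const double cut = ri + radii[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xi + ri * px[k], qy = yi + ri * py[k],
                   qz = zi + ri * pz[k];
      bool occluded = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
                     dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < radii[j] * radii[j]) {
          occluded = true;
          break;
        }
      }
      if (!occluded) ++exposed;
    }
    area[i] = 4.0 * M_PI * ri * ri * exposed / n_points;
  }
  return area;
}
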