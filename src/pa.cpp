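#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo projection approximation.
//
// For each orientation: draw a uniform random rotation (Shoemake quaternion),
// project every atom as a disk of radius r_i + probe onto the viewing plane,
// and estimate the union area by uniform rejection sampling inside the
// bounding box of the disks.  Uses R's RNG so set.seed() governs the result.
//
// Returns the per-orientation projected areas in A^2.

// [[Rcpp::export]]
NumericVector cpp_pa_areas(NumericMatrix coords, NumericVector radii,
                           int nOrientations, int nSamples) {
  const int n = coords.nrow();
  if (radii.size() != n)
    stop("radii length must match atom count");
  NumericVector areas(nOrientations);
  RNGScope scope;
  std::vector<double> px(n), py(n), r2(n);

  for (int o = 0; o < nOrientations; ++o) {
    double u1 = unif_rand(), u2 = unif_rand(), u3 = unif_rand();
    double q0 = std::sqrt(1.0 - u1) * std::sin(2.0 * M_PI * u2);
    double q1 = std::sqrt(1.0 - u1) * std::cos(2.0 * M_PI * u2);
    double q2 = std::sqrt(u1) * std::sin(2.0 * M_PI * u3);
    double q3 = std::sqrt(u1) * std::cos(2.0 * M_PI * u3);
    // first two rows of the rotation matrix give the projection plane
    double r11 = 1 - 2 * (q2 * q2 + q3 * q3), r12 = 2 * (q1 * q2 - q0 * q3),
           r13 = 2 * (q1 * q3 + q0 * q2);
    double r21 = 2 * (q1 * q2 + q0 * q3), r22 = 1 - 2 * (q1 * q1 + q3 * q3),
           r23 = 2 * (q2 * q3 - q0 * q1);

    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
      px[i] = r11 * x + r12 * y + r13 * z;
      py[i] = r21 * x + r22 * y + r23 * z;
      r2[i] = radii[i] * radii[i];
      xmin = std::min(xmin, px[i] - radii[i]);
      xmax = std::max(xmax, px[i] + radii[i]);
      ymin = std::min(ymin, py[i] - radii[i]);
      ymax = std::max(ymax, py[i] + radii[i]);
    }
    const double boxArea = (xmax - xmin) * (ymax - ymin);
    int hits = 0;
    for (int s = 0; s < nSamples; ++s) {
      double sx = xmin + unif_rand() * (xmax - xmin);
      double sy = ymin + unif_rand() * (ymax - ymin);
      for (int i = 0; i < n; ++i) {
        double dx = sx - px[i], dy = sy - py[i];
        if (dx * dx + dy * dy <= r2[i]) { ++hits; break; }
      }
    }
    areas[o] = boxArea * (double)hits / (double)nSamples;
  }
  return areas;
}
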