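// Point-in-watertight-mesh test by ray-casting parity with Moller-Trumbore
// intersection; the ray direction is fixed and slightly irrational to avoid
// edge/vertex degeneracies on axis-aligned meshes.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix P) {
  int nf = F.nrow(), np = P.nrow();
  const double dx = 0.5408231, dy = 0.8017013, dz = 0.2543391; // unnormalised
  LogicalVector inside(np);
  for (int p = 0; p < np; ++p) {
    double ox = P(p, 0), oy = P(p, 1), oz = P(p, 2);
    int hits = 0;
    for (int t = 0; t < nf; ++t) {
      int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
      double e1x = V(b, 0) - V(a, 0), e1y = V(b, 1) - V(a, 1),
             e1z = V(b, 2) - V(a, 2);
      double e2x = V(c, 0) - V(a, 0), e2y = V(c, 1) - V(a, 1),
             e2z = V(c, 2) - V(a, 2);
      double hx = dy * e2z - dz * e2y, hy = dz * e2x - dx * e2z,
             hz = dx * e2y - dy * e2x;
      double det = e1x * hx + e1y * hy + e1z * hz;
      if (std::fabs(det) < 1e-14) continue;
      double inv = 1.0 / det;
      double sx = ox - V(a, 0), sy = oy - V(a, 1), sz = oz - V(a, 2);
      double u = (sx * hx + sy * hy + sz * hz) * inv;
      if (u < 0.0 || u > 1.0) continue;
      double qx = sy * e1z - sz * e1y, qy = sz * e1x - sx * e1z,
             qz = sx * e1y - sy * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < 0.0 || u + v > 1.0) continue;
      double tt = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (tt > 1e-12) ++hits;
    }
    inside[p] = (hits % 2) == 1;
  }
  return inside;
}
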