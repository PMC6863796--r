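// Nearest-neighbour queries from set A to set B via a uniform cell list
// over B; used for contact maps, ECM-strut focality and placement checks.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_nearest(NumericVector ax, NumericVector ay, NumericVector az,
                 NumericVector bx, NumericVector by, NumericVector bz,
                 double range) {
  int na = ax.size(), nb = bx.size();
  IntegerVector idx(na, 0);
  NumericVector dist(na, R_PosInf);
  if (nb == 0 || na == 0)
    return List::create(_["index"] = idx, _["dist"] = dist);
  double xmin = bx[0], ymin = by[0], zmin = bz[0];
  for (int i = 1; i < nb; ++i) {
    xmin = std::min(xmin, (double)bx[i]);
    ymin = std::min(ymin, (double)by[i]);
    zmin = std::min(zmin, (double)bz[i]);
  }
  double h = range > 0 ? range : 1.0;
  // hash grid
  auto key = [&](double x, double y, double z) {
    long ix = (long)std::floor((x - xmin) / h);
    long iy = (long)std::floor((y - ymin) / h);
    long iz = (long)std::floor((z - zmin) / h);
    return ix * 73856093L ^ iy * 19349663L ^ iz * 83492791L;
  };
  std::vector<std::pair<long, int> > cells(nb);
  for (int i = 0; i < nb; ++i)
    cells[i] = std::make_pair(key(bx[i], by[i], bz[i]), i);
  // simple approach: for each a, scan the 27 neighbouring cells
  std::vector<long> ks(nb);
  std::vector<int> order(nb);
  for (int i = 0; i < nb; ++i) { ks[i] = cells[i].first; order[i] = i; }
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return ks[a] < ks[b]; });
  std::vector<long> sorted_keys(nb);
  for (int i = 0; i < nb; ++i) sorted_keys[i] = ks[order[i]];
  auto scan_cell = [&](long k, double pax, double pay, double paz,
                       double& bestd, int& besti) {
    auto lo = std::lower_bound(sorted_keys.begin(), sorted_keys.end(), k);
    for (auto it = lo; it != sorted_keys.end() && *it == k; ++it) {
      int j = order[it - sorted_keys.begin()];
      double dx = pax - bx[j], dy = pay - by[j], dz = paz - bz[j];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < bestd) { bestd = d; besti = j; }
    }
  };
  for (int i = 0; i < na; ++i) {
    double bestd = R_PosInf;
    int besti = -1;
    long ix = (long)std::floor((ax[i] - xmin) / h);
    long iy = (long)std::floor((ay[i] - ymin) / h);
    long iz = (long)std::floor((az[i] - zmin) / h);
    for (long dx = -1; dx <= 1; ++dx)
      for (long dy = -1; dy <= 1; ++dy)
        for (long dz = -1; dz <= 1; ++dz) {
          long k = (ix + dx) * 73856093L ^ (iy + dy) * 19349663L ^
                   (iz + dz) * 83492791L;
          scan_cell(k, ax[i], ay[i], az[i], bestd, besti);
        }
    if (besti >= 0 && bestd <= range) {
      idx[i] = besti + 1;
      dist[i] = bestd;
    }
  }
  return List::create(_["index"] = idx, _["dist"] = dist);
}

// Brute-force nearest distance from each A point to any B point (no range
// limit); nb is expected to be modest.
// [[Rcpp::export]]
NumericVector cpp_nearest_dist(NumericVector ax, NumericVector ay,
                               NumericVector az, NumericVector bx,
                               NumericVector by, NumericVector bz) {
  int na = ax.size(), nb = bx.size();
  NumericVector dist(na, R_PosInf);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = ax[i] - bx[j], dy = ay[i] - by[j], dz = az[i] - bz[j];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    dist[i] = std::sqrt(best);
  }
  return dist;
}
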