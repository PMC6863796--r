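// Agent-sphere rasterisation onto a regular voxel grid plus 6-connected
// flood fill used for lumen/exterior classification and leak detection.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Marks voxels whose centre lies inside any agent sphere as wall (1) and
// records the covering agent with the nearest centre (1-based; 0 = none).
// [[Rcpp::export]]
List cpp_voxelize(NumericVector px, NumericVector py, NumericVector pz,
                  NumericVector rad, double x0, double y0, double z0,
                  double h, int nx, int ny, int nz) {
  size_t ncell = (size_t)nx * ny * nz;
  IntegerVector flags(ncell, 0);
  IntegerVector owner(ncell, 0);
  std::vector<double> best(ncell, 1e30);
  int n = px.size();
  for (int a = 0; a < n; ++a) {
    double r = rad[a];
    int ix0 = std::max(0, (int)std::floor((px[a] - r - x0) / h));
    int ix1 = std::min(nx - 1, (int)std::floor((px[a] + r - x0) / h));
    int iy0 = std::max(0, (int)std::floor((py[a] - r - y0) / h));
    int iy1 = std::min(ny - 1, (int)std::floor((py[a] + r - y0) / h));
    int iz0 = std::max(0, (int)std::floor((pz[a] - r - z0) / h));
    int iz1 = std::min(nz - 1, (int)std::floor((pz[a] + r - z0) / h));
    double r2 = r * r;
    for (int iz = iz0; iz <= iz1; ++iz) {
      double dz = z0 + (iz + 0.5) * h - pz[a];
      for (int iy = iy0; iy <= iy1; ++iy) {
        double dy = y0 + (iy + 0.5) * h - py[a];
        for (int ix = ix0; ix <= ix1; ++ix) {
          double dx = x0 + (ix + 0.5) * h - px[a];
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= r2) {
            size_t c = ((size_t)iz * ny + iy) * nx + ix;
            flags[c] = 1;
            if (d2 < best[c]) { best[c] = d2; owner[c] = a + 1; }
          }
        }
      }
    }
  }
  return List::create(_["flags"] = flags, _["owner"] = owner);
}

// 6-connected flood fill over cells with flags == 0, from 0-based seed
// indices; returns logical reached mask.
// [[Rcpp::export]]
LogicalVector cpp_flood(IntegerVector flags, int nx, int ny, int nz,
                        IntegerVector seeds) {
  size_t ncell = (size_t)nx * ny * nz;
  std::vector<char> vis(ncell, 0);
  std::queue<int> q;
  for (int s = 0; s < seeds.size(); ++s) {
    int c = seeds[s];
    if (c >= 0 && (size_t)c < ncell && flags[c] == 0 && !vis[c]) {
      vis[c] = 1;
      q.push(c);
    }
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!q.empty()) {
    int c = q.front(); q.pop();
    int iz = c / (nx * ny), rem = c % (nx * ny), iy = rem / nx, ix = rem % nx;
    for (int k = 0; k < 6; ++k) {
      int jx = ix + dx[k], jy = iy + dy[k], jz = iz + dz[k];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
        continue;
      int cc = (jz * ny + jy) * nx + jx;
      if (!vis[cc] && flags[cc] == 0) { vis[cc] = 1; q.push(cc); }
    }
  }
  LogicalVector out(ncell);
  for (size_t i = 0; i < ncell; ++i) out[i] = vis[i] != 0;
  return out;
}

// Sub-voxel wall-link fractions for interpolated bounce-back: for every
// fluid cell with a solid neighbour along a D3Q19 link, the fraction of the
// link at which it first crosses an agent-sphere surface (using the same
// effective radii as the rasterisation). 0 where unknown.
// [[Rcpp::export]]
NumericVector cpp_link_fractions(NumericVector px, NumericVector py,
                                 NumericVector pz, NumericVector rad,
                                 double x0, double y0, double z0, double h,
                                 int nx, int ny, int nz,
                                 IntegerVector flags) {
  const int CX[19] = {0, 1, -1, 0, 0, 0, 0, 1, -1, 1, -1, 1, -1, 1, -1,
                      0, 0, 0, 0};
  const int CY[19] = {0, 0, 0, 1, -1, 0, 0, 1, -1, -1, 1, 0, 0, 0, 0,
                      1, -1, 1, -1};
  const int CZ[19] = {0, 0, 0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, -1, 1,
                      1, -1, -1, 1};
  size_t ncell = (size_t)nx * ny * nz;
  size_t nxny = (size_t)nx * ny;
  NumericVector q(ncell * 19, 0.0);
  int n = px.size();
  if (n == 0) return q;

  // uniform bins over agents
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, (double)rad[i]);
  double bin = std::max(2.0 * rmax, 2.0 * h);
  double bx0 = px[0], by0 = py[0], bz0 = pz[0];
  double bx1 = px[0], by1 = py[0], bz1 = pz[0];
  for (int i = 1; i < n; ++i) {
    bx0 = std::min(bx0, (double)px[i]); bx1 = std::max(bx1, (double)px[i]);
    by0 = std::min(by0, (double)py[i]); by1 = std::max(by1, (double)py[i]);
    bz0 = std::min(bz0, (double)pz[i]); bz1 = std::max(bz1, (double)pz[i]);
  }
  int gx = (int)((bx1 - bx0) / bin) + 3, gy = (int)((by1 - by0) / bin) + 3,
      gz = (int)((bz1 - bz0) / bin) + 3;
  std::vector<int> head((size_t)gx * gy * gz, -1), nxt(n, -1);
  auto bidx = [&](double x, double y, double z) {
    int ix = std::max(0, std::min(gx - 1, (int)((x - bx0) / bin) + 1));
    int iy = std::max(0, std::min(gy - 1, (int)((y - by0) / bin) + 1));
    int iz = std::max(0, std::min(gz - 1, (int)((z - bz0) / bin) + 1));
    return ((size_t)iz * gy + iy) * gx + ix;
  };
  for (int i = 0; i < n; ++i) {
    size_t b = bidx(px[i], py[i], pz[i]);
    nxt[i] = head[b];
    head[b] = i;
  }

  const int* fl = INTEGER(flags);
  for (size_t c = 0; c < ncell; ++c) {
    if (fl[c] == 1) continue;
    int iz = (int)(c / nxny);
    int rem = (int)(c % nxny);
    int iy = rem / nx, ix = rem % nx;
    double P0x = x0 + (ix + 0.5) * h, P0y = y0 + (iy + 0.5) * h,
           P0z = z0 + (iz + 0.5) * h;
    for (int i = 1; i < 19; ++i) {
      int jx = ix + CX[i], jy = iy + CY[i], jz = iz + CZ[i];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
        continue;
      size_t cn = ((size_t)jz * nxny + (size_t)jy * nx + jx);
      if (fl[cn] != 1) continue;
      double Dx = CX[i] * h, Dy = CY[i] * h, Dz = CZ[i] * h;
      double best = 2.0;
      // scan agent bins around the link midpoint
      double mx = P0x + 0.5 * Dx, my = P0y + 0.5 * Dy, mz = P0z + 0.5 * Dz;
      int cbx = (int)((mx - bx0) / bin) + 1, cby = (int)((my - by0) / bin) + 1,
          cbz = (int)((mz - bz0) / bin) + 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int bxx = cbx + dx, byy = cby + dy, bzz = cbz + dz;
            if (bxx < 0 || byy < 0 || bzz < 0 || bxx >= gx || byy >= gy ||
                bzz >= gz)
              continue;
            for (int a = head[((size_t)bzz * gy + byy) * gx + bxx]; a >= 0;
                 a = nxt[a]) {
              double ox = P0x - px[a], oy = P0y - py[a], oz = P0z - pz[a];
              double A = Dx * Dx + Dy * Dy + Dz * Dz;
              double B = 2.0 * (ox * Dx + oy * Dy + oz * Dz);
              double C0 = ox * ox + oy * oy + oz * oz - rad[a] * rad[a];
              double disc = B * B - 4.0 * A * C0;
              if (disc < 0.0) continue;
              double sq = std::sqrt(disc);
              double t1 = (-B - sq) / (2.0 * A);
              double t2 = (-B + sq) / (2.0 * A);
              double t = (t1 > 1e-9) ? t1 : ((t2 > 1e-9) ? t2 : -1.0);
              if (t > 0.0 && t < best) best = t;
            }
          }
      if (best <= 1.0) q[c * 19 + i] = best;
    }
  }
  return q;
}
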