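#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Volumes are [z, x, y] column-major: idx = z + nz*(x + nx*y).

static inline bool in_vol(int z, int x, int y, int nz, int nx, int ny) {
  return z >= 0 && z < nz && x >= 0 && x < nx && y >= 0 && y < ny;
}

static const int N6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};

// [[Rcpp::export]]
NumericVector cpp_median3(NumericVector vol, int nz, int nx, int ny, int radius) {
  if (radius <= 0) return clone(vol);
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        buf.clear();
        for (int dy = -radius; dy <= radius; ++dy) {
          int yy = y + dy; if (yy < 0 || yy >= ny) continue;
          for (int dx = -radius; dx <= radius; ++dx) {
            int xx = x + dx; if (xx < 0 || xx >= nx) continue;
            for (int dz = -radius; dz <= radius; ++dz) {
              int zz = z + dz; if (zz < 0 || zz >= nz) continue;
              buf.push_back(vol[zz + (size_t)nz * (xx + (size_t)nx * yy)]);
            }
          }
        }
        size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        double med = buf[m];
        if (buf.size() % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m);
          med = 0.5 * (med + lo);
        }
        out[z + (size_t)nz * (x + (size_t)nx * y)] = med;
      }
  return out;
}

// surface voxels: mask voxels with >= 1 of their 6-neighbours outside the
// mask (volume borders count as outside)
// [[Rcpp::export]]
LogicalVector cpp_surface6(LogicalVector mask, int nz, int nx, int ny) {
  LogicalVector out(mask.size());
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (x + (size_t)nx * y);
        if (!mask[i]) continue;
        bool surf = false;
        for (int k = 0; k < 6 && !surf; ++k) {
          int zz = z + N6[k][0], xx = x + N6[k][1], yy = y + N6[k][2];
          if (!in_vol(zz, xx, yy, nz, nx, ny) ||
              !mask[zz + (size_t)nz * (xx + (size_t)nx * yy)])
            surf = true;
        }
        out[i] = surf;
      }
  return out;
}

// 26-connectivity component labelling (BFS); labels 1..n, 0 = background
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, int nz, int nx, int ny) {
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < (size_t)mask.size(); ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      size_t j = stack.back(); stack.pop_back();
      int z = j % nz, x = (j / nz) % nx, y = j / ((size_t)nz * nx);
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          for (int dz = -1; dz <= 1; ++dz) {
            if (!dz && !dx && !dy) continue;
            int zz = z + dz, xx = x + dx, yy = y + dy;
            if (!in_vol(zz, xx, yy, nz, nx, ny)) continue;
            size_t q = zz + (size_t)nz * (xx + (size_t)nx * yy);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  return lab;
}

// geodesic (conditional) dilation of seeds inside cand, 6-connectivity,
// level-by-level BFS capped at max_iter iterations
// [[Rcpp::export]]
LogicalVector cpp_geodesic_dilate(LogicalVector seeds, LogicalVector cand,
                                  int nz, int nx, int ny, int max_iter) {
  LogicalVector out = clone(seeds);
  std::vector<size_t> frontier, nextf;
  for (size_t i = 0; i < (size_t)seeds.size(); ++i)
    if (seeds[i]) frontier.push_back(i);
  for (int it = 0; it < max_iter && !frontier.empty(); ++it) {
    nextf.clear();
    for (size_t fi = 0; fi < frontier.size(); ++fi) {
      size_t j = frontier[fi];
      int z = j % nz, x = (j / nz) % nx, y = j / ((size_t)nz * nx);
      for (int k = 0; k < 6; ++k) {
        int zz = z + N6[k][0], xx = x + N6[k][1], yy = y + N6[k][2];
        if (!in_vol(zz, xx, yy, nz, nx, ny)) continue;
        size_t q = zz + (size_t)nz * (xx + (size_t)nx * yy);
        if (cand[q] && !out[q]) { out[q] = true; nextf.push_back(q); }
      }
    }
    frontier.swap(nextf);
  }
  return out;
}

static inline void gradient_at(const double *v, int z, int x, int y,
                               int nz, int nx, int ny, double g[3]) {
  size_t s = (size_t)nz;
  size_t i = z + s * (x + (size_t)nx * y);
  int zl = std::max(z - 1, 0), zh = std::min(z + 1, nz - 1);
  int xl = std::max(x - 1, 0), xh = std::min(x + 1, nx - 1);
  int yl = std::max(y - 1, 0), yh = std::min(y + 1, ny - 1);
  g[0] = (v[zh + s * (x + (size_t)nx * y)] - v[zl + s * (x + (size_t)nx * y)]) / (zh - zl > 0 ? zh - zl : 1);
  g[1] = (v[z + s * (xh + (size_t)nx * y)] - v[z + s * (xl + (size_t)nx * y)]) / (xh - xl > 0 ? xh - xl : 1);
  g[2] = (v[z + s * (x + (size_t)nx * yh)] - v[z + s * (x + (size_t)nx * yl)]) / (yh - yl > 0 ? yh - yl : 1);
  (void)i;
}

// gradient magnitudes at the boundary voxels of cand (candidate voxels with
// at least one non-candidate 6-neighbour); used to pick the vote threshold
// [[Rcpp::export]]
NumericVector cpp_boundary_gradients(NumericVector vol, LogicalVector cand,
                                     int nz, int nx, int ny) {
  std::vector<double> mags;
  const double *v = vol.begin();
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (x + (size_t)nx * y);
        if (!cand[i]) continue;
        bool bnd = false;
        for (int k = 0; k < 6 && !bnd; ++k) {
          int zz = z + N6[k][0], xx = x + N6[k][1], yy = y + N6[k][2];
          if (!in_vol(zz, xx, yy, nz, nx, ny) ||
              !cand[zz + (size_t)nz * (xx + (size_t)nx * yy)])
            bnd = true;
        }
        if (!bnd) continue;
        double g[3];
        gradient_at(v, z, x, y, nz, nx, ny, g);
        mags.push_back(std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]));
      }
  return wrap(mags);
}

// cone voting: every boundary voxel of cand with gradient magnitude >= g0
// casts total weight 1, spread uniformly over the voxels of a cone of
// half-angle theta and length L opening along the inward gradient direction
// (from the bright wall toward the dark lumen); votes land in candidate
// voxels only
// [[Rcpp::export]]
NumericVector cpp_cone_vote(NumericVector vol, LogicalVector cand,
                            int nz, int nx, int ny,
                            double theta_deg, int L, double g0) {
  NumericVector votes(vol.size());
  const double *v = vol.begin();
  double cost = std::cos(theta_deg * M_PI / 180.0);
  double cost2 = cost * cost;
  double L2 = (double)L * L;
  std::vector<size_t> landing;
  landing.reserve(4096);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x)
      for (int z = 0; z < nz; ++z) {
        size_t i = z + (size_t)nz * (x + (size_t)nx * y);
        if (!cand[i]) continue;
        bool bnd = false;
        for (int k = 0; k < 6 && !bnd; ++k) {
          int zz = z + N6[k][0], xx = x + N6[k][1], yy = y + N6[k][2];
          if (!in_vol(zz, xx, yy, nz, nx, ny) ||
              !cand[zz + (size_t)nz * (xx + (size_t)nx * yy)])
            bnd = true;
        }
        if (!bnd) continue;
        double g[3];
        gradient_at(v, z, x, y, nz, nx, ny, g);
        double mag = std::sqrt(g[0]*g[0] + g[1]*g[1] + g[2]*g[2]);
        if (mag < g0 || mag <= 0) continue;
        double u0 = -g[0] / mag, u1 = -g[1] / mag, u2 = -g[2] / mag;
        int count = 0;
        landing.clear();
        for (int dy = -L; dy <= L; ++dy)
          for (int dx = -L; dx <= L; ++dx)
            for (int dz = -L; dz <= L; ++dz) {
              if (!dz && !dx && !dy) continue;
              double n2 = (double)dz*dz + (double)dx*dx + (double)dy*dy;
              if (n2 > L2) continue;
              double dot = dz * u0 + dx * u1 + dy * u2;
              if (dot <= 0 || dot * dot < cost2 * n2) continue;
              int zz = z + dz, xx = x + dx, yy = y + dy;
              if (!in_vol(zz, xx, yy, nz, nx, ny)) continue;
              ++count;
              size_t q = zz + (size_t)nz * (xx + (size_t)nx * yy);
              if (cand[q]) landing.push_back(q);
            }
        if (count == 0) continue;
        double w = 1.0 / count;
        for (size_t k = 0; k < landing.size(); ++k) votes[landing[k]] += w;
      }
  return votes;
}
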