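#ifndef SPECIMEN3D_MESHTOOLS_H
#define SPECIMEN3D_MESHTOOLS_H

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>

namespace s3d {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};

inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? a * (1.0 / n) : Vec3(0, 0, 0);
}

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time Collision Detection.
inline Vec3 closest_point_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

// Uniform-grid acceleration structure for closest-point-on-mesh queries.
struct TriGrid {
  std::vector<Vec3> va, vb, vc;   // triangle corners
  Vec3 gmin;
  double h;                        // cell size (cubic cells)
  int nx, ny, nz;
  std::vector<std::vector<int> > cells;
  mutable std::vector<int> stamp;
  mutable int cur_stamp;

  void build(const Rcpp::NumericMatrix& V, const Rcpp::IntegerMatrix& F) {
    int m = F.nrow();
    va.resize(m); vb.resize(m); vc.resize(m);
    Vec3 lo(1e300, 1e300, 1e300), hi(-1e300, -1e300, -1e300);
    for (int i = 0; i < V.nrow(); ++i) {
      lo.x = std::min(lo.x, V(i, 0)); lo.y = std::min(lo.y, V(i, 1)); lo.z = std::min(lo.z, V(i, 2));
      hi.x = std::max(hi.x, V(i, 0)); hi.y = std::max(hi.y, V(i, 1)); hi.z = std::max(hi.z, V(i, 2));
    }
    for (int f = 0; f < m; ++f) {
      int i0 = F(f, 0), i1 = F(f, 1), i2 = F(f, 2);
      va[f] = Vec3(V(i0, 0), V(i0, 1), V(i0, 2));
      vb[f] = Vec3(V(i1, 0), V(i1, 1), V(i1, 2));
      vc[f] = Vec3(V(i2, 0), V(i2, 1), V(i2, 2));
    }
    Vec3 ext = hi - lo;
    double diag = norm(ext);
    if (diag <= 0) diag = 1.0;
    // target roughly a few triangles per cell, grid capped at 96^3
    double target = diag / std::max(8.0, std::cbrt((double)std::max(m, 1)) * 1.5);
    h = std::max(target, diag / 96.0);
    gmin = lo - Vec3(h, h, h) * 0.5;
    nx = std::max(1, (int)std::ceil((ext.x + h) / h));
    ny = std::max(1, (int)std::ceil((ext.y + h) / h));
    nz = std::max(1, (int)std::ceil((ext.z + h) / h));
    cells.assign((size_t)nx * ny * nz, std::vector<int>());
    for (int f = 0; f < m; ++f) {
      Vec3 tlo = va[f], thi = va[f];
      const Vec3* pts[3] = { &va[f], &vb[f], &vc[f] };
      for (int k = 1; k < 3; ++k) {
        tlo.x = std::min(tlo.x, pts[k]->x); tlo.y = std::min(tlo.y, pts[k]->y); tlo.z = std::min(tlo.z, pts[k]->z);
        thi.x = std::max(thi.x, pts[k]->x); thi.y = std::max(thi.y, pts[k]->y); thi.z = std::max(thi.z, pts[k]->z);
      }
      int ix0 = cell_of(tlo.x, gmin.x, nx), ix1 = cell_of(thi.x, gmin.x, nx);
      int iy0 = cell_of(tlo.y, gmin.y, ny), iy1 = cell_of(thi.y, gmin.y, ny);
      int iz0 = cell_of(tlo.z, gmin.z, nz), iz1 = cell_of(thi.z, gmin.z, nz);
      for (int ix = ix0; ix <= ix1; ++ix)
        for (int iy = iy0; iy <= iy1; ++iy)
          for (int iz = iz0; iz <= iz1; ++iz)
            cells[idx(ix, iy, iz)].push_back(f);
    }
    stamp.assign(m, -1);
    cur_stamp = 0;
  }

  int cell_of(double x, double o, int n) const {
    int c = (int)std::floor((x - o) / h);
    return std::min(std::max(c, 0), n - 1);
  }
  size_t idx(int ix, int iy, int iz) const {
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * iz);
  }

  // closest point to p; returns squared distance, sets out + face index
  double query(const Vec3& p, Vec3& out, int& face) const {
    ++cur_stamp;
    int cx = cell_of(p.x, gmin.x, nx);
    int cy = cell_of(p.y, gmin.y, ny);
    int cz = cell_of(p.z, gmin.z, nz);
    double best = std::numeric_limits<double>::infinity();
    face = -1;
    Vec3 cc(gmin.x + (cx + 0.5) * h, gmin.y + (cy + 0.5) * h, gmin.z + (cz + 0.5) * h);
    double d0 = norm(p - cc);
    int rmax = std::max(std::max(nx, ny), nz);
    for (int r = 0; r <= rmax; ++r) {
      // conservative lower bound on distance to any triangle in ring r
      double lb = (r - 1) * h - d0;
      if (face >= 0 && lb * lb > best) break;
      bool any = false;
      int x0 = cx - r, x1 = cx + r, y0 = cy - r, y1 = cy + r, z0 = cz - r, z1 = cz + r;
      for (int ix = std::max(0, x0); ix <= std::min(nx - 1, x1); ++ix)
        for (int iy = std::max(0, y0); iy <= std::min(ny - 1, y1); ++iy)
          for (int iz = std::max(0, z0); iz <= std::min(nz - 1, z1); ++iz) {
            bool on_ring = (ix == x0 || ix == x1 || iy == y0 || iy == y1 || iz == z0 || iz == z1);
            if (!on_ring) continue;
            any = true;
            const std::vector<int>& lst = cells[idx(ix, iy, iz)];
            for (size_t q = 0; q < lst.size(); ++q) {
              int f = lst[q];
              if (stamp[f] == cur_stamp) continue;
              stamp[f] = cur_stamp;
              Vec3 cp = closest_point_triangle(p, va[f], vb[f], vc[f]);
              Vec3 d = p - cp;
              double d2 = dot(d, d);
              if (d2 < best || (d2 == best && f < face)) {
                best = d2; out = cp; face = f;
              }
            }
          }
      if (!any && face >= 0) break;
    }
    return best;
  }
};

} // namespace s3d

#endif
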