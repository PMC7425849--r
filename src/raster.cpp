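#include "meshtools.h"
using namespace Rcpp;
using namespace s3d;

// Pinhole rasterizer with z-buffer, flat per-face Lambertian shading.
//
// Camera model: x_cam = R x_world + t, z forward; u = fx*x/z + cx, v = fy*y/z + cy.
// Pixel (row i, col j), 0-based, has center (u, v) = (j + 0.5, i + 0.5).
// Lights are directions in the CAMERA frame (unit vectors pointing from the
// surface toward the light), so the rig travels with the camera as on a real
// turntable where the specimen rotates and the softboxes stay put.
//
// Returns linear-light RGB in [0,1] (H x W x 3), camera-depth buffer (H x W,
// Inf = background) and 0-based face-id buffer (-1 = background).
// [[Rcpp::export(name = ".cpp_render")]]
List cpp_render(NumericMatrix V, IntegerMatrix F, NumericMatrix Rw2c,
                NumericVector tvec, double fx, double fy, double cx, double cy,
                int width, int height, NumericMatrix face_rgb,
                double ambient, double diffuse, NumericMatrix lights_cam,
                bool want_color) {
  const int m = F.nrow();
  const double znear = 1e-6;
  NumericVector depth((size_t)width * height, R_PosInf);
  IntegerVector faceid((size_t)width * height, -1);
  NumericVector rgb;
  if (want_color) rgb = NumericVector((size_t)width * height * 3, 0.0);

  // camera position in world coords: c = -R^T t
  Vec3 camw(
    -(Rw2c(0, 0) * tvec[0] + Rw2c(1, 0) * tvec[1] + Rw2c(2, 0) * tvec[2]),
    -(Rw2c(0, 1) * tvec[0] + Rw2c(1, 1) * tvec[1] + Rw2c(2, 1) * tvec[2]),
    -(Rw2c(0, 2) * tvec[0] + Rw2c(1, 2) * tvec[1] + Rw2c(2, 2) * tvec[2]));

  // light directions rotated into world frame: l_w = R^T l_cam
  int nl = lights_cam.nrow();
  std::vector<Vec3> lw(nl);
  for (int l = 0; l < nl; ++l) {
    Vec3 lc(lights_cam(l, 0), lights_cam(l, 1), lights_cam(l, 2));
    lw[l] = Vec3(
      Rw2c(0, 0) * lc.x + Rw2c(1, 0) * lc.y + Rw2c(2, 0) * lc.z,
      Rw2c(0, 1) * lc.x + Rw2c(1, 1) * lc.y + Rw2c(2, 1) * lc.z,
      Rw2c(0, 2) * lc.x + Rw2c(1, 2) * lc.y + Rw2c(2, 2) * lc.z);
  }

  const size_t plane = (size_t)width * height;
  for (int f = 0; f < m; ++f) {
    Vec3 w[3], c[3];
    double u[3], v[3], iz[3];
    bool ok = true;
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k);
      w[k] = Vec3(V(vi, 0), V(vi, 1), V(vi, 2));
      c[k] = Vec3(
        Rw2c(0, 0) * w[k].x + Rw2c(0, 1) * w[k].y + Rw2c(0, 2) * w[k].z + tvec[0],
        Rw2c(1, 0) * w[k].x + Rw2c(1, 1) * w[k].y + Rw2c(1, 2) * w[k].z + tvec[1],
        Rw2c(2, 0) * w[k].x + Rw2c(2, 1) * w[k].y + Rw2c(2, 2) * w[k].z + tvec[2]);
      if (c[k].z <= znear) { ok = false; break; }
      u[k] = fx * c[k].x / c[k].z + cx;
      v[k] = fy * c[k].y / c[k].z + cy;
      iz[k] = 1.0 / c[k].z;
    }
    if (!ok) continue;

    double area2 = (u[1] - u[0]) * (v[2] - v[0]) - (u[2] - u[0]) * (v[1] - v[0]);
    if (std::fabs(area2) < 1e-12) continue;

    double shade = 1.0, col[3] = {1, 1, 1};
    if (want_color) {
      Vec3 n = normalize(cross(w[1] - w[0], w[2] - w[0]));
      Vec3 cen = (w[0] + w[1] + w[2]) * (1.0 / 3.0);
      if (dot(n, camw - cen) < 0) n = n * (-1.0); // face the camera (two-sided)
      double dsum = 0;
      for (int l = 0; l < nl; ++l) dsum += std::max(0.0, dot(n, lw[l]));
      if (nl > 0) dsum /= nl;
      shade = ambient + diffuse * dsum;
      for (int ch = 0; ch < 3; ++ch)
        col[ch] = std::min(1.0, std::max(0.0, face_rgb(f, ch) * shade));
    }

    int j0 = std::max(0, (int)std::floor(std::min(std::min(u[0], u[1]), u[2]) - 0.5));
    int j1 = std::min(width - 1, (int)std::ceil(std::max(std::max(u[0], u[1]), u[2]) - 0.5));
    int i0 = std::max(0, (int)std::floor(std::min(std::min(v[0], v[1]), v[2]) - 0.5));
    int i1 = std::min(height - 1, (int)std::ceil(std::max(std::max(v[0], v[1]), v[2]) - 0.5));
    double inv_area = 1.0 / area2;

    for (int i = i0; i <= i1; ++i) {
      double py = i + 0.5;
      for (int j = j0; j <= j1; ++j) {
        double px = j + 0.5;
        double w0 = ((u[1] - px) * (v[2] - py) - (u[2] - px) * (v[1] - py)) * inv_area;
        double w1 = ((u[2] - px) * (v[0] - py) - (u[0] - px) * (v[2] - py)) * inv_area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double zi = w0 * iz[0] + w1 * iz[1] + w2 * iz[2];
        double z = 1.0 / zi;
        size_t pix = (size_t)i + (size_t)height * j; // column-major (H x W)
        if (z < depth[pix]) {
          depth[pix] = z;
          faceid[pix] = f;
          if (want_color)
            for (int ch = 0; ch < 3; ++ch) rgb[pix + plane * ch] = col[ch];
        }
      }
    }
  }

  List out = List::create(_["depth"] = depth, _["faceid"] = faceid);
  if (want_color) out["rgb"] = rgb;
  return out;
}

// Rasterize UV triangles into a texel grid: per texel the owning face (0-based,
// -1 uncovered) and its barycentric coordinates. uv is (3*m) x 2, rows grouped
// per face (corners in face order). Texel (row i, col j) 0-based has UV center
// u = (j+0.5)/S, v = 1 - (i+0.5)/S (v-origin bottom-left, raster row 0 on top).
// [[Rcpp::export(name = ".cpp_uv_rasterize")]]
List cpp_uv_rasterize(NumericMatrix uv, int nfaces, int size) {
  IntegerVector faceid((size_t)size * size, -1);
  NumericVector bary((size_t)size * size * 3, 0.0);
  const size_t plane = (size_t)size * size;

  for (int f = 0; f < nfaces; ++f) {
    double u[3], v[3];
    for (int k = 0; k < 3; ++k) {
      u[k] = uv(3 * f + k, 0) * size;          // texel x
      v[k] = (1.0 - uv(3 * f + k, 1)) * size;  // texel row
    }
    double area2 = (u[1] - u[0]) * (v[2] - v[0]) - (u[2] - u[0]) * (v[1] - v[0]);
    if (std::fabs(area2) < 1e-12) continue;
    double inv_area = 1.0 / area2;
    int j0 = std::max(0, (int)std::floor(std::min(std::min(u[0], u[1]), u[2]) - 0.5));
    int j1 = std::min(size - 1, (int)std::ceil(std::max(std::max(u[0], u[1]), u[2]) - 0.5));
    int i0 = std::max(0, (int)std::floor(std::min(std::min(v[0], v[1]), v[2]) - 0.5));
    int i1 = std::min(size - 1, (int)std::ceil(std::max(std::max(v[0], v[1]), v[2]) - 0.5));
    for (int i = i0; i <= i1; ++i) {
      double py = i + 0.5;
      for (int j = j0; j <= j1; ++j) {
        double px = j + 0.5;
        double w0 = ((u[1] - px) * (v[2] - py) - (u[2] - px) * (v[1] - py)) * inv_area;
        double w1 = ((u[2] - px) * (v[0] - py) - (u[0] - px) * (v[2] - py)) * inv_area;
        double w2 = 1.0 - w0 - w1;
        double tol = -1e-9;
        if (w0 < tol || w1 < tol || w2 < tol) continue;
        size_t pix = (size_t)i + (size_t)size * j;
        if (faceid[pix] == -1) { // first-come; charts must not overlap anyway
          faceid[pix] = f;
          bary[pix] = w0; bary[pix + plane] = w1; bary[pix + 2 * plane] = w2;
        }
      }
    }
  }
  return List::create(_["faceid"] = faceid, _["bary"] = bary);
}
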