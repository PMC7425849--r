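#include "meshtools.h"
using namespace Rcpp;
using namespace s3d;

// One view's contribution to projective texture baking.
//
// P, N: surface point and unit normal per covered texel (t x 3, world/model mm).
// img: linear-light RGB raster (H x W x 3, column-major R array).
// mask: H x W, > 0.5 where the image shows the specimen.
// depthbuf: H x W camera-space depth of the mesh rendered from this pose.
// A texel gathers this view iff its point projects inside the frame, onto a
// masked pixel, passes the depth test (not occluded) and faces the camera;
// the blend weight is cos^2 of the view angle. accum/wsum are updated in place.
// [[Rcpp::export(name = ".cpp_bake_accumulate")]]
void cpp_bake_accumulate(NumericMatrix P, NumericMatrix N, NumericVector img,
                         NumericVector mask, NumericMatrix Rw2c, NumericVector tvec,
                         double fx, double fy, double cx, double cy,
                         int width, int height, NumericVector depthbuf,
                         double depth_tol_rel, double depth_tol_abs,
                         NumericMatrix accum, NumericVector wsum,
                         IntegerVector vcount) {
  int t = P.nrow();
  const size_t plane = (size_t)width * height;
  Vec3 camw(
    -(Rw2c(0, 0) * tvec[0] + Rw2c(1, 0) * tvec[1] + Rw2c(2, 0) * tvec[2]),
    -(Rw2c(0, 1) * tvec[0] + Rw2c(1, 1) * tvec[1] + Rw2c(2, 1) * tvec[2]),
    -(Rw2c(0, 2) * tvec[0] + Rw2c(1, 2) * tvec[1] + Rw2c(2, 2) * tvec[2]));

  for (int i = 0; i < t; ++i) {
    Vec3 p(P(i, 0), P(i, 1), P(i, 2));
    double xc = Rw2c(0, 0) * p.x + Rw2c(0, 1) * p.y + Rw2c(0, 2) * p.z + tvec[0];
    double yc = Rw2c(1, 0) * p.x + Rw2c(1, 1) * p.y + Rw2c(1, 2) * p.z + tvec[1];
    double zc = Rw2c(2, 0) * p.x + Rw2c(2, 1) * p.y + Rw2c(2, 2) * p.z + tvec[2];
    if (zc <= 1e-6) continue;
    double u = fx * xc / zc + cx;
    double v = fy * yc / zc + cy;
    if (u < 0.5 || u > width - 0.5 || v < 0.5 || v > height - 0.5) continue;
    int jn = std::min(width - 1, std::max(0, (int)std::floor(u)));
    int in_ = std::min(height - 1, std::max(0, (int)std::floor(v)));
    size_t pix = (size_t)in_ + (size_t)height * jn;
    if (mask[pix] <= 0.5) continue;
    double d = depthbuf[pix];
    if (!(zc <= d * (1.0 + depth_tol_rel) + depth_tol_abs)) continue; // occluded
    Vec3 nrm(N(i, 0), N(i, 1), N(i, 2));
    double cosang = dot(nrm, normalize(camw - p));
    if (cosang <= 0.05) continue; // grazing or back-facing
    double w = cosang * cosang;

    // bilinear sample (pixel centers at integer+0.5)
    double gx = u - 0.5, gy = v - 0.5;
    int x0 = (int)std::floor(gx), y0 = (int)std::floor(gy);
    double fxw = gx - x0, fyw = gy - y0;
    x0 = std::min(width - 2, std::max(0, x0));
    y0 = std::min(height - 2, std::max(0, y0));
    for (int ch = 0; ch < 3; ++ch) {
      size_t base = plane * ch;
      double c00 = img[base + (size_t)y0 + (size_t)height * x0];
      double c01 = img[base + (size_t)y0 + (size_t)height * (x0 + 1)];
      double c10 = img[base + (size_t)(y0 + 1) + (size_t)height * x0];
      double c11 = img[base + (size_t)(y0 + 1) + (size_t)height * (x0 + 1)];
      double cval = (1 - fyw) * ((1 - fxw) * c00 + fxw * c01)
                  + fyw * ((1 - fxw) * c10 + fxw * c11);
      accum(i, ch) += w * cval;
    }
    wsum[i] += w;
    vcount[i] += 1;
  }
}
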