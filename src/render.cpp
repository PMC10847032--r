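// Pinhole z-buffer rasterizer for triangle meshes given in CAMERA frame
// (x right, y down, z along the optical axis, all mm). Depth is the z
// coordinate; 1/z is interpolated across each triangle (perspective
// correct). Pixel (r, c) corresponds to image-plane coordinates
// u = c - 1, v = r - 1 (0-based pixel centers).
#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_render_depth")]]
NumericMatrix cpp_render_depth(NumericMatrix V, IntegerMatrix F,
                               double fx, double fy, double cx, double cy,
                               int width, int height,
                               double znear, double zfar) {
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix depth(height, width);
  std::fill(depth.begin(), depth.end(), INF);

  int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    int i0 = F(f, 0) - 1, i1 = F(f, 1) - 1, i2 = F(f, 2) - 1;
    double z0 = V(i0, 2), z1 = V(i1, 2), z2 = V(i2, 2);
    if (z0 <= 1e-9 || z1 <= 1e-9 || z2 <= 1e-9) continue;      // behind camera
    if (z0 < znear && z1 < znear && z2 < znear) continue;
    if (z0 > zfar && z1 > zfar && z2 > zfar) continue;
    double u0 = fx * V(i0, 0) / z0 + cx, v0 = fy * V(i0, 1) / z0 + cy;
    double u1 = fx * V(i1, 0) / z1 + cx, v1 = fy * V(i1, 1) / z1 + cy;
    double u2 = fx * V(i2, 0) / z2 + cx, v2 = fy * V(i2, 1) / z2 + cy;
    double area = (u1 - u0) * (v2 - v0) - (u2 - u0) * (v1 - v0);
    if (std::fabs(area) < 1e-12) continue;                      // degenerate
    int cmin = (int)std::ceil(std::min(u0, std::min(u1, u2)));
    int cmax = (int)std::floor(std::max(u0, std::max(u1, u2)));
    int rmin = (int)std::ceil(std::min(v0, std::min(v1, v2)));
    int rmax = (int)std::floor(std::max(v0, std::max(v1, v2)));
    if (cmin < 0) cmin = 0;
    if (rmin < 0) rmin = 0;
    if (cmax > width - 1) cmax = width - 1;
    if (rmax > height - 1) rmax = height - 1;
    if (cmin > cmax || rmin > rmax) continue;
    double w0 = 1.0 / z0, w1 = 1.0 / z1, w2 = 1.0 / z2;
    double inv_area = 1.0 / area;
    for (int r = rmin; r <= rmax; ++r) {
      double v = (double)r;
      for (int c = cmin; c <= cmax; ++c) {
        double u = (double)c;
        double b0 = ((u1 - u) * (v2 - v) - (u2 - u) * (v1 - v)) * inv_area;
        double b1 = ((u2 - u) * (v0 - v) - (u0 - u) * (v2 - v)) * inv_area;
        double b2 = 1.0 - b0 - b1;
        if (b0 < 0 || b1 < 0 || b2 < 0) continue;
        double z = 1.0 / (b0 * w0 + b1 * w1 + b2 * w2);
        if (z < znear || z > zfar) continue;
        if (z < depth(r, c)) depth(r, c) = z;
      }
    }
  }
  for (int i = 0; i < depth.size(); ++i)
    if (!std::isfinite(depth[i])) depth[i] = NA_REAL;
  return depth;
}
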