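#ifndef MV_GEOMETRY_H
#define MV_GEOMETRY_H

#include "mv_common.h"

// Microaneurysm channel: rectangular parent duct (periodic in x, width R2
// along y, depth along z) with a saccular body -- a circular bulge in the
// x-y plane extruded through the full channel depth -- opening through a
// neck of half-width `h` in the y = R2 wall, centred at x = xc.
struct ChannelGeom {
  double L = 0;      // x period
  double R2 = 0;     // duct width (y)
  double depth = 0;  // duct depth (z)
  bool has_body = false;
  double xc = 0, yc = 0, R = 0, h = 0;

  // 0 = outside, 1 = parent lumen, 2 = body lumen
  int classify(double x, double y, double z) const {
    if (z < 0 || z > depth) return 0;
    if (y >= 0 && y <= R2) return 1;
    if (has_body && y > R2) {
      double dx = x - xc, dy = y - yc;
      if (dx * dx + dy * dy <= R * R) return 2;
    }
    return 0;
  }

  // closest point on the 2-D lumen boundary (x-y cross-section) to (x, y)
  void closest2d(double x, double y, double &qx, double &qy) const {
    double bd = 1e300;
    // bottom wall y = 0
    qx = x; qy = 0.0; bd = std::fabs(y);
    auto consider = [&](double cx, double cy) {
      double d = std::hypot(x - cx, y - cy);
      if (d < bd) { bd = d; qx = cx; qy = cy; }
    };
    if (!has_body) {
      consider(x, R2);
      return;
    }
    // top wall segments flanking the neck
    if (x <= xc - h) consider(x, R2); else consider(xc - h, R2);
    if (x >= xc + h) consider(x, R2); else consider(xc + h, R2);
    // body arc (only the part above the wall plane)
    double dx = x - xc, dy = y - yc;
    double r = std::hypot(dx, dy);
    if (r > 1e-12) {
      double ax = xc + R * dx / r, ay = yc + R * dy / r;
      if (ay >= R2) consider(ax, ay);
    }
  }
};

#endif
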