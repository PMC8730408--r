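#include <Rcpp.h>
#include "geometry.h"

using namespace Rcpp;

ChannelGeom geom_from_vec(NumericVector g) {
  ChannelGeom cg;
  cg.L = g["L"];
  cg.R2 = g["R2"];
  cg.depth = g["depth"];
  cg.has_body = g["has_body"] > 0.5;
  cg.xc = g["xc"];
  cg.yc = g["yc"];
  cg.R = g["R"];
  cg.h = g["h"];
  return cg;
}

// [[Rcpp::export]]
IntegerVector cpp_classify_points(NumericVector geom, NumericMatrix pts) {
  ChannelGeom cg = geom_from_vec(geom);
  int n = pts.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = cg.classify(pts(i, 0), pts(i, 1), pts(i, 2));
  return out;
}

// 3-D distance from each point to the lumen surface (positive outside the
// lumen); used to lay down the frozen wall-particle shell.
// [[Rcpp::export]]
NumericVector cpp_lumen_distance(NumericVector geom, NumericMatrix pts) {
  ChannelGeom cg = geom_from_vec(geom);
  int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    bool in2d = cg.classify(x, y, 0.5 * cg.depth) > 0;
    double qx, qy;
    cg.closest2d(x, y, qx, qy);
    double d2 = std::hypot(x - qx, y - qy);
    double dz = 0.0;
    if (z < 0) dz = -z;
    else if (z > cg.depth) dz = z - cg.depth;
    if (in2d) {
      // inside the cross-section: outside only if beyond a depth wall
      out[i] = (dz > 0) ? dz : -std::min(d2, std::min(z, cg.depth - z));
    } else {
      out[i] = (dz > 0) ? std::hypot(d2, dz) : d2;
    }
  }
  return out;
}
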