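#include <Rcpp.h>
#include <map>
#include <array>
#include <utility>
#include "mv_common.h"

using namespace Rcpp;

// Closed triangulations with an arbitrary, exact vertex count are built by
// spreading N points quasi-uniformly on the unit sphere (Fibonacci lattice +
// pairwise-repulsion relaxation) and triangulating them with an incremental
// convex hull. Shape mapping (oblate, biconcave) happens in R afterwards and
// preserves the topology.

static std::vector<Vec3> fibonacci_sphere(int n) {
  std::vector<Vec3> p(n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    p[i] = v3(r * std::cos(phi), r * std::sin(phi), z);
  }
  return p;
}

// Tangential inverse-square repulsion between all point pairs, projected back
// to the sphere each sweep; equilibrates edge lengths before triangulation.
static void relax_on_sphere(std::vector<Vec3> &p, int iters, double step) {
  int n = (int)p.size();
  std::vector<Vec3> f(n);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) f[i] = v3(0, 0, 0);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        Vec3 d = p[i] - p[j];
        double r2 = dot(d, d) + 1e-12;
        Vec3 fr = (1.0 / (r2 * std::sqrt(r2))) * d;
        f[i] = f[i] + fr;
        f[j] = f[j] - fr;
      }
    }
    double s = step / n; // mean-field scaling keeps the move size n-independent
    for (int i = 0; i < n; ++i) {
      Vec3 q = p[i] + s * f[i];
      double nn = norm(q);
      p[i] = (1.0 / nn) * q;
    }
  }
}

// Incremental convex hull for points in near-convex position. Every sphere
// point is an extreme point of the set, so all n points end up as hull
// vertices; a dropped point is reported as an error.
static std::vector<std::array<int, 3>> convex_hull(const std::vector<Vec3> &p) {
  int n = (int)p.size();
  if (n < 4) stop("convex hull needs at least 4 points");
  struct Face {
    int a, b, c;
    bool alive;
  };
  std::vector<Face> faces;
  // initial tetrahedron: points 0, most distant from 0, most distant from
  // line, most distant from plane
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1;
  for (int i = 1; i < n; ++i) {
    double d = norm(p[i] - p[i0]);
    if (d > best) { best = d; i1 = i; }
  }
  best = -1;
  Vec3 e0 = p[i1] - p[i0];
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double d = norm(cross(e0, p[i] - p[i0]));
    if (d > best) { best = d; i2 = i; }
  }
  Vec3 nrm0 = cross(e0, p[i2] - p[i0]);
  best = -1;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double d = std::fabs(dot(nrm0, p[i] - p[i0]));
    if (d > best) { best = d; i3 = i; }
  }
  if (best < 1e-12) stop("degenerate point set: all points coplanar");
  // orient the 4 faces outward w.r.t. the tetrahedron centroid
  Vec3 cen = 0.25 * (p[i0] + p[i1] + p[i2] + p[i3]);
  auto add_face = [&](int a, int b, int c) {
    Vec3 nn = cross(p[b] - p[a], p[c] - p[a]);
    if (dot(nn, p[a] - cen) < 0) std::swap(b, c);
    faces.push_back(Face{a, b, c, true});
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;
  for (int ip = 0; ip < n; ++ip) {
    if (used[ip]) continue;
    used[ip] = true;
    // visible faces
    std::vector<int> vis;
    for (int f = 0; f < (int)faces.size(); ++f) {
      if (!faces[f].alive) continue;
      Vec3 nn = cross(p[faces[f].b] - p[faces[f].a], p[faces[f].c] - p[faces[f].a]);
      if (dot(nn, p[ip] - p[faces[f].a]) > 1e-12) vis.push_back(f);
    }
    if (vis.empty())
      stop("hull construction dropped a point (non-extreme); relax the point set");
    // horizon = undirected edges appearing exactly once among visible faces,
    // kept in the visible face's winding so new faces stay outward
    std::map<std::pair<int, int>, int> cnt;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int a = vv[e], b = vv[(e + 1) % 3];
        cnt[std::make_pair(std::min(a, b), std::max(a, b))] += 1;
      }
    }
    std::vector<std::pair<int, int>> horizon;
    for (int f : vis) {
      int vv[3] = {faces[f].a, faces[f].b, faces[f].c};
      for (int e = 0; e < 3; ++e) {
        int a = vv[e], b = vv[(e + 1) % 3];
        if (cnt[std::make_pair(std::min(a, b), std::max(a, b))] == 1)
          horizon.push_back(std::make_pair(a, b));
      }
      faces[f].alive = false;
    }
    for (auto &e : horizon) faces.push_back(Face{e.first, e.second, ip, true});
  }
  std::vector<std::array<int, 3>> out;
  for (auto &f : faces)
    if (f.alive) out.push_back({f.a, f.b, f.c});
  return out;
}

// [[Rcpp::export]]
List cpp_sphere_mesh(int n, int relax_iters, double relax_step) {
  if (n < 4) stop("need at least 4 vertices");
  std::vector<Vec3> p = fibonacci_sphere(n);
  relax_on_sphere(p, relax_iters, relax_step);
  std::vector<std::array<int, 3>> f = convex_hull(p);
  NumericMatrix V(n, 3);
  for (int i = 0; i < n; ++i) {
    V(i, 0) = p[i].x;
    V(i, 1) = p[i].y;
    V(i, 2) = p[i].z;
  }
  IntegerMatrix F((int)f.size(), 3);
  for (int i = 0; i < (int)f.size(); ++i) {
    F(i, 0) = f[i][0] + 1;
    F(i, 1) = f[i][1] + 1;
    F(i, 2) = f[i][2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
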