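#include <Rcpp.h>
#include <array>
#include "mv_common.h"
#include "membrane.h"
#include "geometry.h"

using namespace Rcpp;

ChannelGeom geom_from_vec(NumericVector g);     // geometry.cpp
MembraneTopo topo_from_list(List tl);           // membrane.cpp

// ---------------------------------------------------------------------------
// DPD engine. One call advances the system `nsteps` steps with the modified
// velocity-Verlet scheme (lambda = 1/2):
//   x(t+dt) = x + dt v + dt^2/2 f/m
//   v~      = v + lambda dt f/m            (used for force evaluation)
//   f(t+dt) = f(x(t+dt), v~)
//   v(t+dt) = v + dt/2 (f(t) + f(t+dt))/m
// Pairwise forces: Groot-Warren conservative/dissipative/random triplet with
// w_C = 1 - r/rc and w_R = (1 - r/rc)^s, w_D = w_R^2, sigma^2 = 2 gamma kBT;
// optional Morse attraction between membrane vertices of distinct RBCs.
// Walls: frozen particles plus bounce-back (position reflected about the
// closest lumen surface point, velocity reversed). Membrane impermeability:
// solvent displacement segments are tested against membrane triangles and
// reflected, with the opposite impulse applied to the face vertices.
// ---------------------------------------------------------------------------

struct EngineBox {
  double lo[3], hi[3];
  bool per[3];
  double len(int k) const { return hi[k] - lo[k]; }
};

static inline void rng_unpack(NumericVector rs, Pcg32 &rng) {
  rng.state = ((uint64_t)(uint32_t)rs[0] << 32) | (uint64_t)(uint32_t)rs[1];
  rng.inc = ((uint64_t)(uint32_t)rs[2] << 32) | (uint64_t)(uint32_t)rs[3];
}
static inline NumericVector rng_pack(const Pcg32 &rng) {
  NumericVector rs(4);
  rs[0] = (double)(uint32_t)(rng.state >> 32);
  rs[1] = (double)(uint32_t)(rng.state & 0xffffffffULL);
  rs[2] = (double)(uint32_t)(rng.inc >> 32);
  rs[3] = (double)(uint32_t)(rng.inc & 0xffffffffULL);
  return rs;
}

// uniform cell grid with optional periodicity per axis
struct CellGrid {
  int nc[3];
  double csz[3];
  EngineBox box;
  std::vector<int> head, nxt;

  void build(const std::vector<Vec3> &pos, const EngineBox &b, double cell_min) {
    box = b;
    for (int k = 0; k < 3; ++k) {
      nc[k] = std::max(1, (int)std::floor(b.len(k) / cell_min));
      csz[k] = b.len(k) / nc[k];
    }
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    nxt.assign(pos.size(), -1);
    for (int i = 0; i < (int)pos.size(); ++i) {
      int c = cell_of(pos[i]);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
  int clampc(int v, int k) const {
    if (box.per[k]) {
      v %= nc[k];
      if (v < 0) v += nc[k];
    } else {
      if (v < 0) v = 0;
      if (v >= nc[k]) v = nc[k] - 1;
    }
    return v;
  }
  int cell_of(Vec3 p) const {
    double q[3] = {p.x, p.y, p.z};
    int ix[3];
    for (int k = 0; k < 3; ++k)
      ix[k] = clampc((int)std::floor((q[k] - box.lo[k]) / csz[k]), k);
    return (ix[2] * nc[1] + ix[1]) * nc[0] + ix[0];
  }
};

static inline Vec3 min_image(Vec3 d, const EngineBox &box) {
  if (box.per[0]) d.x -= box.len(0) * std::round(d.x / box.len(0));
  if (box.per[1]) d.y -= box.len(1) * std::round(d.y / box.len(1));
  if (box.per[2]) d.z -= box.len(2) * std::round(d.z / box.len(2));
  return d;
}

// Moller-Trumbore segment/triangle intersection; t in (0, 1].
static bool seg_tri(Vec3 o, Vec3 d, Vec3 a, Vec3 b, Vec3 c, double &t,
                    double tol = 1e-9) {
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 pv = cross(d, e2);
  double det = dot(e1, pv);
  if (std::fabs(det) < 1e-14) return false;
  double inv = 1.0 / det;
  Vec3 tv = o - a;
  double u = dot(tv, pv) * inv;
  if (u < -tol || u > 1.0 + tol) return false;
  Vec3 qv = cross(tv, e1);
  double v = dot(d, qv) * inv;
  if (v < -tol || u + v > 1.0 + tol) return false;
  t = dot(e2, qv) * inv;
  return t > 0.0 && t <= 1.0;
}

// Continuous collision of a moving point against a linearly deforming
// triangle over one step: all four vertices move linearly in t, so the
// coplanarity function F(t) = [(b-a) x (c-a)] . (p-a) is a cubic in t.
// Roots of F in (0, 1] are located by sign-change bisection on the exact
// cubic (reconstructed from four nodal evaluations) and accepted when the
// point lies inside the triangle at the root.
static bool ccd_point_tri(Vec3 o, Vec3 dp, Vec3 a0, Vec3 da, Vec3 b0,
                          Vec3 db, Vec3 c0, Vec3 dc, double &t_hit) {
  auto Fof = [&](double t) {
    Vec3 a = a0 + t * da, b = b0 + t * db, c = c0 + t * dc;
    Vec3 p = o + t * dp;
    return dot(cross(b - a, c - a), p - a);
  };
  // exact cubic f(t) = d0 + c1 t + c2 t^2 + c3 t^3 through the nodes
  // t = 0, 1/3, 2/3, 1
  double f0 = Fof(0.0), f1 = Fof(1.0 / 3.0), f2 = Fof(2.0 / 3.0),
         f3 = Fof(1.0);
  double d0 = f0;
  double g1 = f1 - f0, g2 = f2 - f0, g3 = f3 - f0;
  double c3 = 4.5 * (g3 + 3.0 * g1 - 3.0 * g2);
  double c2 = 4.5 * (g2 - 2.0 * g1) - c3;
  double c1 = g3 - c2 - c3;
  auto cubic = [&](double t) { return d0 + t * (c1 + t * (c2 + t * c3)); };
  // scan for sign changes on a fine grid, bisect each bracket
  const int ns = 16;
  double t_best = 2.0;
  double prev_t = 0.0, prev_f = f0;
  for (int k = 1; k <= ns; ++k) {
    double tk = (double)k / ns;
    double fk = cubic(tk);
    if ((prev_f <= 0.0) != (fk <= 0.0)) {
      double lo = prev_t, hi = tk, flo = prev_f;
      for (int it = 0; it < 40; ++it) {
        double mid = 0.5 * (lo + hi);
        double fm = cubic(mid);
        if ((flo <= 0.0) == (fm <= 0.0)) {
          lo = mid;
          flo = fm;
        } else {
          hi = mid;
        }
      }
      double tr = 0.5 * (lo + hi);
      if (tr > 1e-12 && tr < t_best) {
        // inside-triangle check at the root
        Vec3 a = a0 + tr * da, b = b0 + tr * db, c = c0 + tr * dc;
        Vec3 p = o + tr * dp;
        Vec3 n = cross(b - a, c - a);
        double nn2 = dot(n, n);
        if (nn2 > 1e-20) {
          Vec3 w = p - a;
          double u = dot(cross(b - a, w), n) / nn2; // coordinate along c
          double v = dot(cross(w, c - a), n) / nn2; // coordinate along b
          if (u >= -1e-6 && v >= -1e-6 && u + v <= 1.0 + 1e-6) t_best = tr;
        }
      }
    }
    prev_t = tk;
    prev_f = fk;
  }
  if (t_best > 1.0) return false;
  t_hit = t_best;
  return true;
}

// [[Rcpp::export]]
List cpp_run_chunk(List state, List topo_list, List inter, List box_list,
                   Nullable<NumericVector> geom_vec, List drive, List opts,
                   int nsteps, double dt) {
  // ---- unpack state ----
  NumericMatrix pos_in = state["pos"], vel_in = state["vel"], f_in = state["force"];
  NumericVector mass = state["mass"];
  IntegerVector type = state["type"], cellid = state["cell"];
  double time = as<double>(state["time"]);
  Pcg32 rng;
  rng_unpack(state["rng"], rng);
  int N = pos_in.nrow();

  std::vector<Vec3> pos(N), vel(N), fold(N), fnew(N), vtil(N), pold(N);
  for (int i = 0; i < N; ++i) {
    pos[i] = v3(pos_in(i, 0), pos_in(i, 1), pos_in(i, 2));
    vel[i] = v3(vel_in(i, 0), vel_in(i, 1), vel_in(i, 2));
    fold[i] = v3(f_in(i, 0), f_in(i, 1), f_in(i, 2));
  }

  // ---- interactions ----
  NumericMatrix amat = inter["a"], gmat = inter["gamma"], smat = inter["sigma"];
  double rc = as<double>(inter["rc"]);
  double sexp = as<double>(inter["s"]);
  bool morse_on = as<bool>(inter["morse_on"]);
  double m_de = as<double>(inter["morse_de"]), m_beta = as<double>(inter["morse_beta"]);
  double m_r0 = as<double>(inter["morse_r0"]), m_rcut = as<double>(inter["morse_rcut"]);
  double rmax = rc;
  if (morse_on && m_rcut > rmax) rmax = m_rcut;
  double rmax2 = rmax * rmax, rc2 = rc * rc;
  double isqdt = 1.0 / std::sqrt(dt);

  // ---- box / geometry ----
  EngineBox box;
  {
    NumericVector lo = box_list["lo"], hi = box_list["hi"];
    LogicalVector per = box_list["periodic"];
    for (int k = 0; k < 3; ++k) {
      box.lo[k] = lo[k];
      box.hi[k] = hi[k];
      box.per[k] = per[k];
    }
  }
  int nrad_chk = (morse_on && m_rcut > rc) ? (int)std::ceil(m_rcut / rc) : 1;
  for (int k = 0; k < 3; ++k) {
    if (box.per[k] && box.len(k) < 2.0 * rmax)
      stop("periodic box extent smaller than twice the interaction cutoff");
    if (box.per[k] &&
        (int)std::floor(box.len(k) / rc) < 2 * nrad_chk + 1)
      stop("periodic box too small for the cell-pair stencil: need at least " +
           std::to_string(2 * nrad_chk + 1) + " grid cells per periodic axis");
  }
  bool has_geom = geom_vec.isNotNull();
  ChannelGeom cg;
  if (has_geom) cg = geom_from_vec(geom_vec.get());

  // ---- membrane topology ----
  bool has_mem = topo_list.size() > 0;
  MembraneTopo topo;
  if (has_mem) topo = topo_from_list(topo_list);
  bool reflect_faces = as<bool>(opts["reflect_faces"]) && has_mem;

  // ---- drive / external ----
  double g_body = as<double>(drive["g"]);
  double p_amp = as<double>(drive["pulse_amp"]);
  double p_per = as<double>(drive["pulse_period"]);
  bool parent_only = as<bool>(drive["parent_only"]);
  bool has_ext = drive.containsElementNamed("ext_force") &&
                 !Rf_isNull(drive["ext_force"]);
  NumericMatrix ext;
  if (has_ext) ext = as<NumericMatrix>(drive["ext_force"]);
  double lang_gamma = as<double>(drive["langevin_gamma"]);
  double lang_kbt = as<double>(drive["langevin_kbt"]);

  double vmax = as<double>(opts["vmax"]);
  double slab0 = as<double>(opts["slab_x0"]), slab1 = as<double>(opts["slab_x1"]);
  bool measure = as<bool>(opts["measure"]);

  CellGrid grid;
  int nrad = (morse_on && m_rcut > rc) ? (int)std::ceil(m_rcut / rc) : 1;

  // triangle grid for face reflection (rebuilt each step)
  CellGrid tgrid;
  std::vector<std::vector<int>> tri_in_cell;

  bool unstable = false;
  long n_rffail = 0;
  double slab_acc = 0.0;
  long slab_cnt = 0;
  int steps_done = 0;
  std::string mem_err;

  // flat copies of the coefficient matrices for the hot loop
  double A_[16], G_[16], S_[16];
  for (int ti = 0; ti < 4; ++ti)
    for (int tj = 0; tj < 4; ++tj) {
      A_[4 * ti + tj] = amat(ti, tj);
      G_[4 * ti + tj] = gmat(ti, tj);
      S_[4 * ti + tj] = smat(ti, tj);
    }
  const double sqrt3 = 1.7320508075688772;
  const double hx = 0.5 * box.len(0), hy = 0.5 * box.len(1),
               hz = 0.5 * box.len(2);
  const int *typep = &type[0];
  const int *cellp = &cellid[0];

  auto pair_kernel = [&](int i, int j, const std::vector<Vec3> &vv) {
    int ti = typep[i], tj = typep[j];
    if ((ti == 1 && tj == 1) || (cellp[i] > 0 && cellp[i] == cellp[j]))
      return;
    double dx = pos[i].x - pos[j].x, dy = pos[i].y - pos[j].y,
           dz = pos[i].z - pos[j].z;
    if (box.per[0]) { if (dx > hx) dx -= 2 * hx; else if (dx < -hx) dx += 2 * hx; }
    if (box.per[1]) { if (dy > hy) dy -= 2 * hy; else if (dy < -hy) dy += 2 * hy; }
    if (box.per[2]) { if (dz > hz) dz -= 2 * hz; else if (dz < -hz) dz += 2 * hz; }
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rmax2 || r2 < 1e-20) return;
    double r = std::sqrt(r2);
    double fmag = 0.0;
    if (r2 < rc2) {
      int tp = 4 * ti + tj;
      double a = A_[tp], gam = G_[tp], sig = S_[tp];
      double wc = 1.0 - r / rc;
      double wr;
      if (sexp == 1.0) wr = wc;
      else if (sexp == 0.5) wr = std::sqrt(wc);
      else if (sexp == 0.25) wr = std::sqrt(std::sqrt(wc));
      else wr = std::pow(wc, sexp);
      double dvr = ((vv[i].x - vv[j].x) * dx + (vv[i].y - vv[j].y) * dy +
                    (vv[i].z - vv[j].z) * dz) / r;
      fmag += a * wc - gam * wr * wr * dvr;
      if (sig > 0) {
        // symmetric uniform pair noise with unit variance (Groot-Warren)
        double th = sqrt3 * (2.0 * rng.unif() - 1.0);
        fmag += sig * wr * th * isqdt;
      }
    }
    if (morse_on && ti == 2 && tj == 2 && r < m_rcut) {
      double eb = std::exp(m_beta * (m_r0 - r));
      fmag += 2.0 * m_beta * m_de * (eb * eb - eb);
    }
    double s = fmag / r;
    fnew[i].x += s * dx; fnew[i].y += s * dy; fnew[i].z += s * dz;
    fnew[j].x -= s * dx; fnew[j].y -= s * dy; fnew[j].z -= s * dz;
  };

  auto compute_forces = [&](double tnow, bool use_vtil) -> bool {
    for (int i = 0; i < N; ++i) fnew[i] = v3(0, 0, 0);
    const std::vector<Vec3> &vv = use_vtil ? vtil : vel;
    grid.build(pos, box, rc);
    // half stencil over cell pairs: self cell + forward neighbour offsets
    std::vector<std::array<int, 3>> offs;
    for (int dz = -nrad; dz <= nrad; ++dz)
      for (int dy = -nrad; dy <= nrad; ++dy)
        for (int dx = -nrad; dx <= nrad; ++dx) {
          if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0))
            offs.push_back({dx, dy, dz});
        }
    int ncx = grid.nc[0], ncy = grid.nc[1], ncz = grid.nc[2];
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          int c = (cz * ncy + cy) * ncx + cx;
          int h0 = grid.head[c];
          if (h0 < 0) continue;
          // within-cell pairs
          for (int i = h0; i >= 0; i = grid.nxt[i])
            for (int j = grid.nxt[i]; j >= 0; j = grid.nxt[j])
              pair_kernel(i, j, vv);
          // forward-neighbour cells
          for (auto &o : offs) {
            int nx = cx + o[0], ny = cy + o[1], nz = cz + o[2];
            if (box.per[0]) nx = (nx + ncx) % ncx;
            else if (nx < 0 || nx >= ncx) continue;
            if (box.per[1]) ny = (ny + ncy) % ncy;
            else if (ny < 0 || ny >= ncy) continue;
            if (box.per[2]) nz = (nz + ncz) % ncz;
            else if (nz < 0 || nz >= ncz) continue;
            int c2 = (nz * ncy + ny) * ncx + nx;
            int h2 = grid.head[c2];
            if (h2 < 0) continue;
            for (int i = h0; i >= 0; i = grid.nxt[i])
              for (int j = h2; j >= 0; j = grid.nxt[j])
                pair_kernel(i, j, vv);
          }
        }
    if (has_mem) {
      MembraneEnergy me = membrane_forces_core(pos, topo, fnew, true);
      if (!me.ok) {
        mem_err = me.err;
        return false;
      }
    }
    // body force (pressure-gradient surrogate) on solvent, optionally only in
    // the parent duct
    if (g_body != 0.0) {
      double scale = 1.0;
      if (p_per > 0 && p_amp > 0)
        scale = 1.0 + p_amp * std::sin(2.0 * M_PI * tnow / p_per);
      for (int i = 0; i < N; ++i) {
        if (type[i] != 0) continue;
        if (parent_only && has_geom &&
            cg.classify(pos[i].x, pos[i].y, pos[i].z) != 1)
          continue;
        fnew[i].x += mass[i] * g_body * scale;
      }
    }
    if (has_ext)
      for (int i = 0; i < N; ++i) {
        fnew[i].x += ext(i, 0);
        fnew[i].y += ext(i, 1);
        fnew[i].z += ext(i, 2);
      }
    if (lang_gamma > 0) {
      double amp = std::sqrt(2.0 * lang_gamma * lang_kbt) * isqdt;
      for (int i = 0; i < N; ++i) {
        if (type[i] == 1) continue;
        fnew[i] = fnew[i] - lang_gamma * vv[i];
        fnew[i].x += amp * rng.normal();
        fnew[i].y += amp * rng.normal();
        fnew[i].z += amp * rng.normal();
      }
    }
    return true;
  };

  // initial forces if caller flagged them stale
  if (as<bool>(state["force_stale"])) {
    if (!compute_forces(time, false)) stop(mem_err);
    std::swap(fold, fnew);
  }

  for (int s = 0; s < nsteps; ++s) {
    // -- drift --
    for (int i = 0; i < N; ++i) {
      pold[i] = pos[i];
      if (type[i] == 1) {
        vtil[i] = v3(0, 0, 0);
        continue;
      }
      double im = 1.0 / mass[i];
      pos[i] = pos[i] + dt * vel[i] + (0.5 * dt * dt * im) * fold[i];
      vtil[i] = vel[i] + (0.5 * dt * im) * fold[i];
    }
    // -- periodic wrap (membrane vertices stay unwrapped so bonded terms
    //    never straddle the seam; the pair kernel min-images them) --
    for (int k = 0; k < 3; ++k) {
      if (!box.per[k]) continue;
      double lo = box.lo[k], Lk = box.len(k);
      for (int i = 0; i < N; ++i) {
        if (type[i] >= 2) continue;
        double *q = (k == 0) ? &pos[i].x : (k == 1 ? &pos[i].y : &pos[i].z);
        if (*q < lo) *q += Lk;
        else if (*q >= lo + Lk) *q -= Lk;
      }
    }
    // -- walls at the lumen surface --
    if (has_geom) {
      const double eps_in = 0.02;
      const double Lx = box.len(0);
      auto xwrapf = [&](double x) {
        if (!box.per[0]) return x;
        return x - Lx * std::floor((x - box.lo[0]) / Lx);
      };
      for (int i = 0; i < N; ++i) {
        if (type[i] == 1) continue;
        double xw = xwrapf(pos[i].x);
        if (cg.classify(xw, pos[i].y, pos[i].z) != 0) continue;
        if (type[i] == 0) {
          // solvent: bounce-back (position reflected, velocity reversed)
          // imposes no-slip together with the frozen wall shell
          Vec3 p = pos[i];
          if (p.z < 0) p.z = -p.z;
          else if (p.z > cg.depth) p.z = 2.0 * cg.depth - p.z;
          if (cg.classify(p.x, p.y, p.z) == 0) {
            double qx, qy;
            cg.closest2d(p.x, p.y, qx, qy);
            p.x = 2.0 * qx - p.x;
            p.y = 2.0 * qy - p.y;
          }
          Vec3 disp = p - pold[i];
          if (cg.classify(p.x, p.y, p.z) != 0 && dot(disp, disp) < 1.0) {
            pos[i] = p;
          } else {
            pos[i] = pold[i]; // deep corner or oversized jump: reject
            ++n_rffail;
          }
          vel[i] = -1.0 * vel[i];
          vtil[i] = -1.0 * vtil[i];
        } else {
          // membrane vertex: project just inside the surface and remove the
          // outward velocity component (hard reflections at re-entrant
          // corners would pump elastic energy); work in wrapped x
          Vec3 p = v3(xw, pos[i].y, pos[i].z);
          if (p.z < eps_in) {
            p.z = eps_in;
            if (vel[i].z < 0) { vel[i].z = 0; vtil[i].z = 0; }
          } else if (p.z > cg.depth - eps_in) {
            p.z = cg.depth - eps_in;
            if (vel[i].z > 0) { vel[i].z = 0; vtil[i].z = 0; }
          }
          if (cg.classify(p.x, p.y, p.z) == 0) {
            double qx, qy;
            cg.closest2d(p.x, p.y, qx, qy);
            double nx = qx - p.x, ny = qy - p.y; // inward
            double nn = std::hypot(nx, ny);
            if (nn > 1e-12) {
              nx /= nn; ny /= nn;
              p.x = qx + eps_in * nx;
              p.y = qy + eps_in * ny;
              double vn = vel[i].x * nx + vel[i].y * ny;
              if (vn < 0) {
                vel[i].x -= vn * nx; vel[i].y -= vn * ny;
                vtil[i].x -= vn * nx; vtil[i].y -= vn * ny;
              }
            }
          }
          if (cg.classify(p.x, p.y, p.z) != 0) {
            pos[i].x += p.x - xw; // corrections mapped back to unwrapped x
            pos[i].y = p.y;
            pos[i].z = p.z;
          } else {
            pos[i] = pold[i];
            vel[i] = -1.0 * vel[i];
            vtil[i] = -1.0 * vtil[i];
            ++n_rffail;
          }
        }
      }
    }
    // -- membrane face reflection for solvent --
    if (reflect_faces) {
      int T = (int)topo.faces.size();
      tgrid.build(pos, box, rc); // reuse cell geometry for binning
      tri_in_cell.assign(tgrid.head.size(), {});
      // per-triangle bounding data for a conservative distance prefilter:
      // centroid (current) and a radius covering both endpoints of every
      // vertex's motion
      std::vector<Vec3> tri_cen(T);
      std::vector<double> tri_rad(T);
      for (int t = 0; t < T; ++t) {
        int ta = topo.faces[t][0], tb = topo.faces[t][1],
            tc = topo.faces[t][2];
        Vec3 cen = (1.0 / 3.0) * (pos[ta] + pos[tb] + pos[tc]);
        double r2m = 0.0;
        for (int v : {ta, tb, tc}) {
          Vec3 d1 = pos[v] - cen;
          Vec3 d2 = pold[v] - cen;
          r2m = std::max(r2m, std::max(dot(d1, d1), dot(d2, d2)));
        }
        tri_cen[t] = cen;
        tri_rad[t] = std::sqrt(r2m);
        tri_in_cell[tgrid.cell_of(cen)].push_back(t);
      }
      // Crossings are detected in each face's co-moving frame (old triangle
      // positions, particle displacement minus face displacement), which
      // catches both particles moving through faces and faces sweeping over
      // slow particles. The particle is then placed back on its original
      // side of the *updated* face plane with a small margin, and the
      // normal component of its face-relative velocity is reversed, with
      // the opposite impulse shared by the face vertices.
      const double eps_f = 0.01;
      for (int i = 0; i < N; ++i) {
        if (type[i] != 0) continue;
        Vec3 o = pold[i];
        Vec3 dseg = min_image(pos[i] - pold[i], box);
        double best_t = 2.0;
        int best_f = -1;
        double q[3] = {o.x, o.y, o.z};
        int ix[3];
        for (int k = 0; k < 3; ++k)
          ix[k] = tgrid.clampc((int)std::floor((q[k] - box.lo[k]) / tgrid.csz[k]), k);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int cz = ix[2] + dz, cy = ix[1] + dy, cx = ix[0] + dx;
              if (box.per[2]) cz = (cz % tgrid.nc[2] + tgrid.nc[2]) % tgrid.nc[2];
              else if (cz < 0 || cz >= tgrid.nc[2]) continue;
              if (box.per[1]) cy = (cy % tgrid.nc[1] + tgrid.nc[1]) % tgrid.nc[1];
              else if (cy < 0 || cy >= tgrid.nc[1]) continue;
              if (box.per[0]) cx = (cx % tgrid.nc[0] + tgrid.nc[0]) % tgrid.nc[0];
              else if (cx < 0 || cx >= tgrid.nc[0]) continue;
              int c = (cz * tgrid.nc[1] + cy) * tgrid.nc[0] + cx;
              for (int t : tri_in_cell[c]) {
                // conservative sphere prefilter: the particle path (length
                // |dseg| from o) cannot touch the triangle's swept volume
                // if it stays outside centroid +/- (radius + path + margin)
                Vec3 dc = min_image(tri_cen[t] - o, box);
                double reach = tri_rad[t] + norm(dseg) + 1e-6;
                if (dot(dc, dc) > reach * reach) continue;
                int ta = topo.faces[t][0], tb = topo.faces[t][1],
                    tc = topo.faces[t][2];
                Vec3 ao = pold[ta];
                Vec3 sh = min_image(ao - o, box) - (ao - o);
                double tt;
                if (ccd_point_tri(o, dseg, ao + sh, pos[ta] - pold[ta],
                                  pold[tb] + sh, pos[tb] - pold[tb],
                                  pold[tc] + sh, pos[tc] - pold[tc], tt) &&
                    tt < best_t) {
                  best_t = tt;
                  best_f = t;
                }
              }
            }
        if (best_f < 0) continue;
        int fa = topo.faces[best_f][0], fb = topo.faces[best_f][1],
            fcv = topo.faces[best_f][2];
        // old plane fixes which side the particle belongs on
        Vec3 ao = pold[fa];
        Vec3 sh = min_image(ao - o, box) - (ao - o);
        Vec3 n_old = cross(pold[fb] - pold[fa], pold[fcv] - pold[fa]);
        double s_old = (dot(o - (ao + sh), n_old) >= 0) ? 1.0 : -1.0;
        // updated plane
        Vec3 nrm = cross(pos[fb] - pos[fa], pos[fcv] - pos[fa]);
        double nn = norm(nrm);
        if (nn < 1e-14) continue;
        Vec3 nh = (1.0 / nn) * nrm;
        Vec3 a_new = pos[fa] + sh;
        // place the particle on its original side with a margin
        double d_side = dot(pos[i] - a_new, nh);
        if (s_old * d_side < eps_f) {
          pos[i] = pos[i] + (s_old * eps_f - d_side) * nh;
        }
        // reverse the approaching normal component of the face-relative
        // velocity (moving-mirror reflection conserves momentum and cannot
        // pump energy)
        Vec3 vf = (1.0 / 3.0) * (vel[fa] + vel[fb] + vel[fcv]);
        double vn = dot(vel[i] - vf, nh);
        if (vn * s_old < 0) {
          vel[i] = vel[i] - 2.0 * vn * nh;
          double vnt = dot(vtil[i] - vf, nh);
          vtil[i] = vtil[i] - 2.0 * vnt * nh;
          double imp = 2.0 * mass[i] * vn / 3.0;
          for (int v : {fa, fb, fcv}) {
            vel[v] = vel[v] + (imp / mass[v]) * nh;
            vtil[v] = vtil[v] + (imp / mass[v]) * nh;
          }
        }
      }
    }
    // -- forces at t+dt, then velocity correction --
    if (!compute_forces(time + dt, true)) {
      unstable = true;
      break;
    }
    double vmx = 0.0;
    for (int i = 0; i < N; ++i) {
      if (type[i] == 1) continue;
      double im = 1.0 / mass[i];
      vel[i] = vel[i] + (0.5 * dt * im) * (fold[i] + fnew[i]);
      double sp = std::fabs(vel[i].x) + std::fabs(vel[i].y) + std::fabs(vel[i].z);
      if (sp > vmx) vmx = sp;
      if (!std::isfinite(fnew[i].x + fnew[i].y + fnew[i].z))
        stop("non-finite force on particle " + std::to_string(i + 1));
    }
    std::swap(fold, fnew);
    time += dt;
    ++steps_done;
    if (measure) {
      double sv = 0;
      long nv = 0;
      for (int i = 0; i < N; ++i)
        if (type[i] == 0 && pos[i].x >= slab0 && pos[i].x < slab1 &&
            (!has_geom || cg.classify(pos[i].x, pos[i].y, pos[i].z) == 1)) {
          sv += vel[i].x;
          ++nv;
        }
      if (nv > 0) {
        slab_acc += sv / nv;
        ++slab_cnt;
      }
    }
    if (vmx > vmax) {
      unstable = true;
      break;
    }
  }

  NumericMatrix pos_out(N, 3), vel_out(N, 3), f_out(N, 3);
  for (int i = 0; i < N; ++i) {
    pos_out(i, 0) = pos[i].x; pos_out(i, 1) = pos[i].y; pos_out(i, 2) = pos[i].z;
    vel_out(i, 0) = vel[i].x; vel_out(i, 1) = vel[i].y; vel_out(i, 2) = vel[i].z;
    f_out(i, 0) = fold[i].x; f_out(i, 1) = fold[i].y; f_out(i, 2) = fold[i].z;
  }
  return List::create(
      _["pos"] = pos_out, _["vel"] = vel_out, _["force"] = f_out,
      _["mass"] = mass, _["type"] = type, _["cell"] = cellid,
      _["time"] = time, _["rng"] = rng_pack(rng), _["force_stale"] = false,
      _["diag"] = List::create(
          _["steps_done"] = steps_done, _["unstable"] = unstable,
          _["mem_err"] = mem_err, _["reflect_fail"] = (double)n_rffail,
          _["inlet_vx"] = (slab_cnt > 0) ? slab_acc / slab_cnt : NA_REAL));
}

// parity ray-cast point-in-mesh test (closed meshes); slightly tilted ray
// avoids edge/vertex grazing
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix V, IntegerMatrix F,
                                 NumericMatrix pts) {
  int T = F.nrow(), n = pts.nrow();
  std::vector<Vec3> vp(V.nrow());
  for (int i = 0; i < V.nrow(); ++i) vp[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  Vec3 dir = v3(0.57735, 0.577349, 0.577352); // irrational-ish direction
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 o = v3(pts(i, 0), pts(i, 1), pts(i, 2));
    int hits = 0;
    for (int t = 0; t < T; ++t) {
      Vec3 a = vp[F(t, 0) - 1], b = vp[F(t, 1) - 1], c = vp[F(t, 2) - 1];
      double tt;
      if (seg_tri(o, 1e6 * dir, a, b, c, tt)) ++hits;
    }
    out[i] = (hits % 2) == 1;
  }
  return out;
}
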