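#include <Rcpp.h>
#include "membrane.h"

using namespace Rcpp;

// Free energy of a membrane network: V_t = V_s + V_b + V_a + V_v.
//   V_s: worm-like-chain attraction + power-law repulsion per edge,
//        V_WLC(l) = (kBT/p) * lm/4 * (3x^2 - 2x^3)/(1 - x), x = l/lm,
//        V_POW(l) = kp / ((m-1) l^(m-1))              (m != 1)
//   V_b: kb * (1 - cos(theta - theta0)) per dihedral
//   V_a: ka (A - A0)^2 / (2 A0) per cell (+ kd local per-triangle term)
//   V_v: kv (V - V0)^2 / (2 V0) per cell
// Forces are exact negative gradients of the implemented energies.

MembraneEnergy membrane_forces_core(const std::vector<Vec3> &pos,
                                    const MembraneTopo &topo,
                                    std::vector<Vec3> &f,
                                    bool want_forces) {
  MembraneEnergy E;

  // --- elastic bonds ---
  for (size_t e = 0; e < topo.edges.size(); ++e) {
    int i = topo.edges[e][0], j = topo.edges[e][1];
    Vec3 d = pos[i] - pos[j];
    double l = norm(d);
    double x = l / topo.lm[e];
    if (x >= 1.0) {
      E.ok = false;
      E.err = "edge " + std::to_string(e + 1) + " at or beyond maximum extension l_m";
      return E;
    }
    double kw = topo.kwlc[e];
    double m = topo.pow_m;
    E.vs += kw * topo.lm[e] * 0.25 * (3.0 * x * x - 2.0 * x * x * x) / (1.0 - x);
    E.vs += topo.kp[e] / ((m - 1.0) * std::pow(l, m - 1.0));
    if (want_forces) {
      // attractive WLC tension and repulsive power-law force along the bond
      double fw = kw * (0.25 / ((1.0 - x) * (1.0 - x)) - 0.25 + x);
      double fp = topo.kp[e] / std::pow(l, m);
      double mag = (fp - fw) / l; // >0 pushes i away from j
      f[i] = f[i] + mag * d;
      f[j] = f[j] - mag * d;
    }
  }

  // --- bending ---
  for (size_t h = 0; h < topo.dihedrals.size(); ++h) {
    int a = topo.dihedrals[h][0], b = topo.dihedrals[h][1];
    int c = topo.dihedrals[h][2], d = topo.dihedrals[h][3];
    Vec3 e = pos[b] - pos[a];
    double le = norm(e);
    Vec3 n1 = cross(pos[b] - pos[a], pos[c] - pos[a]); // tri (a,b,c)
    Vec3 n2 = cross(pos[d] - pos[a], pos[b] - pos[a]); // tri (a,d,b)
    double l1 = dot(n1, n1), l2 = dot(n2, n2);
    if (l1 < 1e-24 || l2 < 1e-24) {
      E.ok = false;
      E.err = "degenerate triangle at dihedral " + std::to_string(h + 1);
      return E;
    }
    double in1 = 1.0 / std::sqrt(l1), in2 = 1.0 / std::sqrt(l2);
    double cs = dot(n1, n2) * in1 * in2;
    double sn = dot(cross(n1, n2), e) * in1 * in2 / le;
    double theta = std::atan2(sn, cs);
    double t0 = topo.theta0[h];
    E.vb += topo.kb[h] * (1.0 - std::cos(theta - t0));
    if (want_forces) {
      double dE = topo.kb[h] * std::sin(theta - t0);
      Vec3 g1 = (1.0 / l1) * n1, g2 = (1.0 / l2) * n2;
      Vec3 eh = (1.0 / le) * e;
      // hinge-angle gradient: grad theta = -(ua, ub, uc, ud) below, so the
      // force -dE * grad theta is +dE times each u term
      Vec3 uc = le * g1;
      Vec3 ud = le * g2;
      Vec3 ua = (dot(pos[c] - pos[b], eh)) * g1 + (dot(pos[d] - pos[b], eh)) * g2;
      Vec3 ub = (-dot(pos[c] - pos[a], eh)) * g1 + (-dot(pos[d] - pos[a], eh)) * g2;
      f[c] = f[c] + dE * uc;
      f[d] = f[d] + dE * ud;
      f[a] = f[a] + dE * ua;
      f[b] = f[b] + dE * ub;
    }
  }

  // --- area and volume constraints per cell ---
  int ncell = (int)topo.A0.size();
  std::vector<double> area(ncell, 0.0), vol(ncell, 0.0);
  for (size_t t = 0; t < topo.faces.size(); ++t) {
    int a = topo.faces[t][0], b = topo.faces[t][1], c = topo.faces[t][2];
    Vec3 n = cross(pos[b] - pos[a], pos[c] - pos[a]);
    int cell = topo.face_cell[t];
    area[cell] += 0.5 * norm(n);
    vol[cell] += dot(pos[a], cross(pos[b], pos[c])) / 6.0;
  }
  for (int cc = 0; cc < ncell; ++cc) {
    double dA = area[cc] - topo.A0[cc];
    double dV = vol[cc] - topo.V0[cc];
    E.va += topo.ka[cc] * dA * dA / (2.0 * topo.A0[cc]);
    E.vv += topo.kv[cc] * dV * dV / (2.0 * topo.V0[cc]);
  }
  bool any_local = !topo.at0.empty();
  for (size_t t = 0; t < topo.faces.size(); ++t) {
    int a = topo.faces[t][0], b = topo.faces[t][1], c = topo.faces[t][2];
    int cell = topo.face_cell[t];
    Vec3 n = cross(pos[b] - pos[a], pos[c] - pos[a]);
    double nn = norm(n);
    if (nn < 1e-12) {
      E.ok = false;
      E.err = "degenerate triangle " + std::to_string(t + 1);
      return E;
    }
    double at = 0.5 * nn;
    double coefl = 0.0;
    if (any_local && topo.kd[cell] > 0) {
      double da = at - topo.at0[t];
      E.va += topo.kd[cell] * da * da / (2.0 * topo.at0[t]);
      coefl = topo.kd[cell] * da / topo.at0[t];
    }
    if (!want_forces) continue;
    double coefA = topo.ka[cell] * (area[cell] - topo.A0[cell]) / topo.A0[cell] + coefl;
    double coefV = topo.kv[cell] * (vol[cell] - topo.V0[cell]) / topo.V0[cell];
    Vec3 nh = (1.0 / nn) * n;
    // grad of triangle area w.r.t. its vertices
    f[a] = f[a] - coefA * (0.5 * cross(pos[b] - pos[c], nh));
    f[b] = f[b] - coefA * (0.5 * cross(pos[c] - pos[a], nh));
    f[c] = f[c] - coefA * (0.5 * cross(pos[a] - pos[b], nh));
    // grad of signed tet volume
    f[a] = f[a] - coefV * ((1.0 / 6.0) * cross(pos[b], pos[c]));
    f[b] = f[b] - coefV * ((1.0 / 6.0) * cross(pos[c], pos[a]));
    f[c] = f[c] - coefV * ((1.0 / 6.0) * cross(pos[a], pos[b]));
  }
  return E;
}

MembraneTopo topo_from_list(List tl) {
  MembraneTopo topo;
  IntegerMatrix ed = tl["edges"];
  NumericVector l0 = tl["l0"], lm = tl["lm"], kp = tl["kp"], kwlc = tl["kwlc"];
  topo.pow_m = as<double>(tl["pow_m"]);
  for (int i = 0; i < ed.nrow(); ++i)
    topo.edges.push_back({ed(i, 0) - 1, ed(i, 1) - 1});
  topo.l0.assign(l0.begin(), l0.end());
  topo.lm.assign(lm.begin(), lm.end());
  topo.kp.assign(kp.begin(), kp.end());
  topo.kwlc.assign(kwlc.begin(), kwlc.end());
  IntegerMatrix dh = tl["dihedrals"];
  NumericVector th0 = tl["theta0"], kb = tl["kb"];
  for (int i = 0; i < dh.nrow(); ++i)
    topo.dihedrals.push_back({dh(i, 0) - 1, dh(i, 1) - 1, dh(i, 2) - 1, dh(i, 3) - 1});
  topo.theta0.assign(th0.begin(), th0.end());
  topo.kb.assign(kb.begin(), kb.end());
  IntegerMatrix fc = tl["faces"];
  IntegerVector fcell = tl["face_cell"];
  for (int i = 0; i < fc.nrow(); ++i) {
    topo.faces.push_back({fc(i, 0) - 1, fc(i, 1) - 1, fc(i, 2) - 1});
    topo.face_cell.push_back(fcell[i] - 1);
  }
  NumericVector A0 = tl["A0"], V0 = tl["V0"], ka = tl["ka"], kv = tl["kv"], kd = tl["kd"];
  topo.A0.assign(A0.begin(), A0.end());
  topo.V0.assign(V0.begin(), V0.end());
  topo.ka.assign(ka.begin(), ka.end());
  topo.kv.assign(kv.begin(), kv.end());
  topo.kd.assign(kd.begin(), kd.end());
  if (tl.containsElementNamed("at0") && !Rf_isNull(tl["at0"])) {
    NumericVector at0 = tl["at0"];
    topo.at0.assign(at0.begin(), at0.end());
  }
  return topo;
}

// [[Rcpp::export]]
List cpp_membrane_forces(NumericMatrix V, List topo_list, bool want_forces) {
  int n = V.nrow();
  std::vector<Vec3> pos(n);
  for (int i = 0; i < n; ++i) pos[i] = v3(V(i, 0), V(i, 1), V(i, 2));
  MembraneTopo topo = topo_from_list(topo_list);
  std::vector<Vec3> f(n, v3(0, 0, 0));
  MembraneEnergy E = membrane_forces_core(pos, topo, f, want_forces);
  if (!E.ok) stop(E.err);
  NumericMatrix F(n, 3);
  if (want_forces)
    for (int i = 0; i < n; ++i) {
      F(i, 0) = f[i].x;
      F(i, 1) = f[i].y;
      F(i, 2) = f[i].z;
    }
  return List::create(_["vs"] = E.vs, _["vb"] = E.vb, _["va"] = E.va,
                      _["vv"] = E.vv, _["forces"] = F);
}
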