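#ifndef MV_MEMBRANE_H
#define MV_MEMBRANE_H

#include <vector>
#include <array>
#include <string>
#include "mv_common.h"

// Bonded topology of one (or many concatenated) closed triangulated
// membranes. Vertex indices are 0-based into the global particle arrays.
struct MembraneTopo {
  // WLC + power-law repulsion bonds
  std::vector<std::array<int, 2>> edges;
  std::vector<double> l0, lm, kp, kwlc; // per edge; kwlc = kBT / p
  double pow_m = 2.0;                   // repulsion exponent (force ~ kp / l^m)
  // dihedral bending: shared edge (a, b), flanks c (tri a,b,c) and d
  std::vector<std::array<int, 4>> dihedrals;
  std::vector<double> theta0, kb; // per dihedral
  // oriented faces grouped per cell for area/volume constraints
  std::vector<std::array<int, 3>> faces;
  std::vector<int> face_cell;              // cell index per face (0-based)
  std::vector<double> at0;                 // per-face reference area (local term)
  std::vector<double> A0, V0, ka, kv, kd;  // per cell
};

struct MembraneEnergy {
  double vs = 0, vb = 0, va = 0, vv = 0;
  bool ok = true;
  std::string err;
};

// Accumulates forces into f (same length as pos); returns energy breakdown.
MembraneEnergy membrane_forces_core(const std::vector<Vec3> &pos,
                                    const MembraneTopo &topo,
                                    std::vector<Vec3> &f,
                                    bool want_forces);

#endif
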