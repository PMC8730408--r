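#ifndef MV_COMMON_H
#define MV_COMMON_H

#include <cstdint>
#include <cmath>
#include <vector>

// Minimal 3-vector helpers used across the compiled core.
struct Vec3 {
  double x, y, z;
};
static inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
static inline Vec3 operator+(Vec3 a, Vec3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline Vec3 operator-(Vec3 a, Vec3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline Vec3 operator*(double s, Vec3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(Vec3 a, Vec3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline Vec3 cross(Vec3 a, Vec3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm(Vec3 a) { return std::sqrt(dot(a, a)); }

// PCG32: small, fast, state is two 64-bit words so checkpoints can carry it
// exactly. Single-threaded use keeps trajectories bit-reproducible per seed.
struct Pcg32 {
  uint64_t state;
  uint64_t inc;

  void seed(uint64_t initstate, uint64_t initseq) {
    state = 0u;
    inc = (initseq << 1u) | 1u;
    next();
    state += initstate;
    next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  // uniform in (0, 1), never exactly 0 (safe for Box-Muller log)
  double unif() { return (next() + 1.0) / 4294967297.0; }
  double normal() {
    // Box-Muller, one value per call (discarding the pair partner keeps the
    // draw sequence independent of call-site pairing)
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

#endif
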