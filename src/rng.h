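#ifndef WAVECOMM_RNG_H
#define WAVECOMM_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded generator (xoshiro256++ seeded via splitmix64).
// Used inside compiled kernels so that results are reproducible from a single
// integer seed independently of R's RNG state, and so that independent streams
// (connectivity / initial conditions / drive) can be spawned cheaply.
struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform in (0, 1] (safe for log())
  inline double unif_pos() {
    return ((next() >> 11) + 1) * 0x1.0p-53;
  }

  inline double expo() { return -std::log(unif_pos()); }

  // Marsaglia polar method
  inline double norm() {
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    return u * std::sqrt(-2.0 * std::log(q) / q);
  }

  // Poisson by Knuth multiplication; adequate for small means (< ~10)
  inline int poisson(double L /* = exp(-lambda) */) {
    int k = 0;
    double p = unif();
    while (p > L) {
      ++k;
      p *= unif();
    }
    return k;
  }
};

#endif
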