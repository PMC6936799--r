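#ifndef CPCH_RNG_H
#define CPCH_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ with splitmix64 seeding: a fast, high-quality generator for
// the Brownian-dynamics simulators. Seeded explicitly so simulated traces
// are reproducible independently of R's RNG state.
struct CpchRng {
  uint64_t s[4];
  bool have_cached;
  double cached;

  explicit CpchRng(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  // standard normal via the ziggurat method (128 layers), with the polar
  // method only in the rare rejection branches' tail
  static const double *zig_x() {
    static double X[130];
    static bool ready = false;
    if (!ready) {
      const double R = 3.442619855899, V = 9.91256303526217e-3;
      X[0] = V / std::exp(-0.5 * R * R);
      X[1] = R;
      X[128] = 0.0;
      for (int i = 2; i < 128; ++i) {
        double xi = X[i - 1];
        X[i] = std::sqrt(-2.0 * std::log(V / xi + std::exp(-0.5 * xi * xi)));
      }
      ready = true;
    }
    return X;
  }

  inline double norm() {
    const double *X = zig_x();
    const double R = 3.442619855899;
    for (;;) {
      const uint64_t r = next();
      const int i = (int) ((r >> 4) & 127);
      const double u = 2.0 * (((r >> 11) + 0.5) * (1.0 / 9007199254740992.0)) - 1.0;
      const double x = u * X[i];
      if (std::fabs(x) < X[i + 1]) return x;
      if (i == 0) {
        // tail beyond R
        double xx, yy;
        do {
          xx = -std::log(unif()) / R;
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return u < 0 ? -(R + xx) : R + xx;
      }
      const double f0 = std::exp(-0.5 * (X[i] * X[i] - x * x));
      const double f1 = std::exp(-0.5 * (X[i + 1] * X[i + 1] - x * x));
      if (f1 + unif() * (f0 - f1) < 1.0) return x;
    }
  }

  // Poisson by Knuth's product method; adequate for the small means
  // (counts per bin well below ~20) arising in photon emission
  inline int pois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {
      const double L = std::exp(-lambda);
      int k = 0;
      double p = 1.0;
      do { ++k; p *= unif(); } while (p > L);
      return k - 1;
    }
    // normal approximation with continuity correction for rare large means
    const double x = lambda + std::sqrt(lambda) * norm() + 0.5;
    return x < 0.0 ? 0 : static_cast<int>(x);
  }
};

#endif
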