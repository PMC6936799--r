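#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include "cpch_rng.h"

using namespace Rcpp;

// Brownian-dynamics photon-emission simulators.
//
// Molecules diffuse in a periodic box; at each sampling step every molecule
// emits Poisson photons with mean given by the 3D Gaussian intensity
// profile(s), then positions are updated with Gaussian increments of
// variance 2*D*dt per axis (emit-then-move convention).
//
// Molecules far from any position where they could emit are advanced
// lazily: Brownian increments compose, so a molecule that provably (to
// ~5 sigma) cannot reach the emission region within k steps is given a
// single Gaussian displacement of variance 2*D*k*dt after k steps. This
// is statistically exact for the emitted photons (the sleep horizon keeps
// excursions to the emission boundary, where the intensity factor is
// already exp(-19), vanishingly improbable) and keeps the spatial
// distribution uniform. A timing wheel schedules the wake-ups.

namespace {

struct Wheel {
  static const int BITS = 16;
  static const int SIZE = 1 << BITS;   // 65536 slots
  std::vector<int> head;               // head[slot] -> molecule index or -1
  std::vector<int> nxt;
  Wheel(int nmol) : head(SIZE, -1), nxt(nmol, -1) {}
  inline void push(int slot, int i) {
    nxt[i] = head[slot];
    head[slot] = i;
  }
};

inline double wrap1(double x, double half, double len) {
  while (x > half) x -= len;
  while (x < -half) x += len;
  return x;
}

} // namespace

// [[Rcpp::export(name = ".sim_trace_cpp")]]
IntegerMatrix sim_trace_cpp(IntegerVector n_mol, NumericVector D,
                            NumericVector epsA_dt, NumericVector epsB_dt,
                            double rA, double zA, double rB, double zB,
                            NumericVector box, double dt, double n_steps_d,
                            double seed) {
  const long long n_steps = (long long) n_steps_d;
  const int n_sp = n_mol.size();
  int nmol = 0;
  for (int q = 0; q < n_sp; ++q) nmol += n_mol[q];
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;

  // emission reach: with u = rho^2/r^2 + z^2/z0^2 (widest channel), the
  // intensity factor is <= exp(-2u); beyond u = 8.5 the expected photon
  // yield over any realistic trace is negligible
  const double Q_ACT = 8.5;
  const double rm = std::max(rA, rB), zm = std::max(zA, zB);
  const double sqQ = std::sqrt(Q_ACT);
  const double ax = sqQ * rm;   // bounding box of the emission ellipsoid
  const double az = sqQ * zm;
  const double irm2 = 1.0 / (rm * rm), izm2 = 1.0 / (zm * zm);
  const bool eqA = (rA == rm && zA == zm);
  const bool eqB = (rB == rm && zB == zm);

  CpchRng rng((uint64_t) seed);

  // coordinates packed per molecule for cache locality
  std::vector<double> P((size_t) 3 * nmol);
  std::vector<double> U(nmol);      // cached ellipsoid coordinate
  std::vector<int> sp(nmol);
  std::vector<long long> last(nmol, 0);
  std::vector<double> sig1(n_sp);
  for (int q = 0; q < n_sp; ++q) sig1[q] = std::sqrt(2.0 * D[q] * dt);

  const double irA2 = 2.0 / (rA * rA), izA2 = 2.0 / (zA * zA);
  const double irB2 = 2.0 / (rB * rB), izB2 = 2.0 / (zB * zB);

  auto ucoord = [&](int i) {
    const double x = P[3 * i], y = P[3 * i + 1], z = P[3 * i + 2];
    return (x * x + y * y) * irm2 + z * z * izm2;
  };

  {
    int i = 0;
    for (int q = 0; q < n_sp; ++q)
      for (int j = 0; j < n_mol[q]; ++j, ++i) {
        sp[i] = q;
        P[3 * i] = (rng.unif() - 0.5) * Lx;
        P[3 * i + 1] = (rng.unif() - 0.5) * Ly;
        P[3 * i + 2] = (rng.unif() - 0.5) * Lz;
        U[i] = ucoord(i);
      }
  }

  Wheel wheel(nmol);
  std::vector<int> active;
  active.reserve(nmol);

  // sleep length from a lower bound on the distance to the emission
  // ellipsoid: the larger of the scaled-ellipsoid bound
  // (sqrt(u) - sqrt(Q)) * r and the Euclidean distance to its bounding box
  auto sleep_steps = [&](int i) -> long long {
    const double u = U[i];
    if (u <= Q_ACT) return 0;
    double e = (std::sqrt(u) - sqQ) * rm;
    const double x = P[3 * i], y = P[3 * i + 1], z = P[3 * i + 2];
    const double ex = std::max(std::fabs(x) - ax, 0.0);
    const double ey = std::max(std::fabs(y) - ax, 0.0);
    const double ez = std::max(std::fabs(z) - az, 0.0);
    const double d2 = ex * ex + ey * ey + ez * ez;
    if (d2 > e * e) e = std::sqrt(d2);
    const double s1 = sig1[sp[i]];
    if (s1 == 0.0) return (long long) (Wheel::SIZE - 1);
    double k = e / (2.5 * s1);
    k *= k;
    if (k < 2.0) return 0;                    // close: treat as active
    long long kk = (long long) k;
    if (kk > Wheel::SIZE - 1) kk = Wheel::SIZE - 1;
    return kk;
  };

  // initial classification
  for (int i = 0; i < nmol; ++i) {
    long long k = sleep_steps(i);
    if (k == 0) active.push_back(i);
    else wheel.push((int) (k & (Wheel::SIZE - 1)), i);
  }

  IntegerMatrix counts(n_steps, 2);
  bool anyB = false;
  for (int q = 0; q < n_sp; ++q) if (epsB_dt[q] > 0) anyB = true;

  for (long long s = 0; s < n_steps; ++s) {
    // wake molecules scheduled for this step
    int slot = (int) (s & (Wheel::SIZE - 1));
    int i = wheel.head[slot];
    wheel.head[slot] = -1;
    while (i >= 0) {
      int nx = wheel.nxt[i];
      long long elapsed = s - last[i];
      if (elapsed > 0) {
        double sd = sig1[sp[i]] * std::sqrt((double) elapsed);
        P[3 * i] = wrap1(P[3 * i] + sd * rng.norm(), hx, Lx);
        P[3 * i + 1] = wrap1(P[3 * i + 1] + sd * rng.norm(), hy, Ly);
        P[3 * i + 2] = wrap1(P[3 * i + 2] + sd * rng.norm(), hz, Lz);
        U[i] = ucoord(i);
      }
      last[i] = s;
      long long k = sleep_steps(i);
      if (k == 0) active.push_back(i);
      else wheel.push((int) ((s + k) & (Wheel::SIZE - 1)), i);
      i = nx;
    }

    // single pass: emit from the position current at this step, then move
    // (molecules are independent, so interleaving per molecule is
    // equivalent to emitting all, then moving all)
    int cA = 0, cB = 0;
    for (size_t a = 0; a < active.size(); ) {
      const int id = active[a];
      const double u = U[id];
      if (u < Q_ACT) {
        const double x = P[3 * id], y = P[3 * id + 1], z = P[3 * id + 2];
        const double rho2 = x * x + y * y, z2 = z * z;
        const double eA = epsA_dt[sp[id]];
        if (eA > 0) {
          const double q = eqA ? 2.0 * u : rho2 * irA2 + z2 * izA2;
          if (q < 2.5 * Q_ACT) cA += rng.pois(eA * std::exp(-q));
        }
        if (anyB) {
          const double eB = epsB_dt[sp[id]];
          if (eB > 0) {
            const double q = eqB ? 2.0 * u : rho2 * irB2 + z2 * izB2;
            if (q < 2.5 * Q_ACT) cB += rng.pois(eB * std::exp(-q));
          }
        }
      }
      const double s1 = sig1[sp[id]];
      if (s1 > 0) {
        P[3 * id] = wrap1(P[3 * id] + s1 * rng.norm(), hx, Lx);
        P[3 * id + 1] = wrap1(P[3 * id + 1] + s1 * rng.norm(), hy, Ly);
        P[3 * id + 2] = wrap1(P[3 * id + 2] + s1 * rng.norm(), hz, Lz);
        U[id] = ucoord(id);
      }
      last[id] = s + 1;
      long long k = sleep_steps(id);
      if (k > 0) {
        active[a] = active.back();
        active.pop_back();
        wheel.push((int) ((s + 1 + k) & (Wheel::SIZE - 1)), id);
        // do not advance a: swapped-in molecule occupies this slot
      } else {
        ++a;
      }
    }
    counts(s, 0) = cA;
    counts(s, 1) = cB;
    if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}

// [[Rcpp::export(name = ".sim_image_cpp")]]
IntegerVector sim_image_cpp(IntegerVector n_mol, NumericVector D,
                            NumericVector eps_dwell,
                            double rA, double zA,
                            NumericVector box,
                            int npx, int npy, int frames,
                            double dx, double dy,
                            double dwell, int retrace_line_steps,
                            int retrace_frame_steps, double seed) {
  const int n_sp = n_mol.size();
  int nmol = 0;
  for (int q = 0; q < n_sp; ++q) nmol += n_mol[q];
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double hx = Lx / 2, hy = Ly / 2, hz = Lz / 2;
  const double Ximg = npx * dx, Yimg = npy * dy;

  const double Q_ACT = 9.5;
  const double ax = std::sqrt(Q_ACT) * rA;
  const double az = std::sqrt(Q_ACT) * zA;
  // emission can happen anywhere the laser scans: pad the scan rectangle
  const double bx = Ximg / 2 + ax, by = Yimg / 2 + ax, bz = az;

  CpchRng rng((uint64_t) seed);

  std::vector<double> X(nmol), Y(nmol), Z(nmol);
  std::vector<int> sp(nmol);
  std::vector<long long> last(nmol, 0);
  std::vector<double> sig1(n_sp);
  for (int q = 0; q < n_sp; ++q) sig1[q] = std::sqrt(2.0 * D[q] * dwell);

  {
    int i = 0;
    for (int q = 0; q < n_sp; ++q)
      for (int j = 0; j < n_mol[q]; ++j, ++i) {
        sp[i] = q;
        X[i] = (rng.unif() - 0.5) * Lx;
        Y[i] = (rng.unif() - 0.5) * Ly;
        Z[i] = (rng.unif() - 0.5) * Lz;
      }
  }

  Wheel wheel(nmol);
  std::vector<int> active;
  active.reserve(nmol);
  std::vector<int> active_pos(nmol, -1);

  auto sleep_steps = [&](int i) -> long long {
    double ex = std::max(std::fabs(X[i]) - bx, 0.0);
    double ey = std::max(std::fabs(Y[i]) - by, 0.0);
    double ez = std::max(std::fabs(Z[i]) - bz, 0.0);
    double e = std::sqrt(ex * ex + ey * ey + ez * ez);
    if (e <= 0) return 0;
    double s1 = sig1[sp[i]];
    if (s1 == 0.0) return (long long) (Wheel::SIZE - 1);
    double k = (e / (2.5 * s1));
    k *= k;
    if (k < 4.0) return 0;
    long long kk = (long long) k;
    if (kk > Wheel::SIZE - 1) kk = Wheel::SIZE - 1;
    return kk;
  };
  auto make_active = [&](int i) {
    active_pos[i] = (int) active.size();
    active.push_back(i);
  };
  auto drop_active = [&](int i) {
    int pos = active_pos[i];
    int lastm = active.back();
    active[pos] = lastm;
    active_pos[lastm] = pos;
    active.pop_back();
    active_pos[i] = -1;
  };
  for (int i = 0; i < nmol; ++i) {
    long long k = sleep_steps(i);
    if (k == 0) make_active(i);
    else wheel.push((int) (k & (Wheel::SIZE - 1)), i);
  }

  const double ir2 = 2.0 / (rA * rA), iz2 = 2.0 / (zA * zA);
  IntegerVector out((R_xlen_t) npx * npy * frames);
  long long s = 0;

  auto advance_step = [&](bool emit, double lx, double ly, int *acc) {
    // wake
    int slot = (int) (s & (Wheel::SIZE - 1));
    int i = wheel.head[slot];
    wheel.head[slot] = -1;
    while (i >= 0) {
      int nx2 = wheel.nxt[i];
      long long elapsed = s - last[i];
      if (elapsed > 0) {
        double sd = sig1[sp[i]] * std::sqrt((double) elapsed);
        X[i] = wrap1(X[i] + sd * rng.norm(), hx, Lx);
        Y[i] = wrap1(Y[i] + sd * rng.norm(), hy, Ly);
        Z[i] = wrap1(Z[i] + sd * rng.norm(), hz, Lz);
      }
      last[i] = s;
      long long k = sleep_steps(i);
      if (k == 0) make_active(i);
      else wheel.push((int) ((s + k) & (Wheel::SIZE - 1)), i);
      i = nx2;
    }
    if (emit) {
      int c = 0;
      for (size_t a = 0; a < active.size(); ++a) {
        int id = active[a];
        double ddx = X[id] - lx, ddy = Y[id] - ly, ddz = Z[id];
        double q = (ddx * ddx + ddy * ddy) * ir2 + ddz * ddz * iz2;
        if (q < 2.5 * Q_ACT) {
          double e = eps_dwell[sp[id]];
          if (e > 0) c += rng.pois(e * std::exp(-q));
        }
      }
      *acc = c;
    }
    // move
    for (size_t a = 0; a < active.size(); ) {
      int id = active[a];
      double s1 = sig1[sp[id]];
      if (s1 > 0) {
        X[id] = wrap1(X[id] + s1 * rng.norm(), hx, Lx);
        Y[id] = wrap1(Y[id] + s1 * rng.norm(), hy, Ly);
        Z[id] = wrap1(Z[id] + s1 * rng.norm(), hz, Lz);
      }
      last[id] = s + 1;
      long long k = sleep_steps(id);
      if (k > 0) {
        drop_active(id);
        wheel.push((int) ((s + 1 + k) & (Wheel::SIZE - 1)), id);
      } else ++a;
    }
    ++s;
  };

  for (int f = 0; f < frames; ++f) {
    for (int iy = 0; iy < npy; ++iy) {
      double ly = -Yimg / 2 + (iy + 0.5) * dy;
      for (int ix = 0; ix < npx; ++ix) {
        double lx = -Ximg / 2 + (ix + 0.5) * dx;
        int c = 0;
        advance_step(true, lx, ly, &c);
        out[(R_xlen_t) f * npx * npy + (R_xlen_t) iy * npx + ix] = c;
      }
      for (int k = 0; k < retrace_line_steps; ++k) advance_step(false, 0, 0, 0);
      Rcpp::checkUserInterrupt();
    }
    for (int k = 0; k < retrace_frame_steps; ++k) advance_step(false, 0, 0, 0);
  }
  out.attr("dim") = IntegerVector::create(npx, npy, frames);
  return out;
}
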