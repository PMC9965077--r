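#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64 core). R's RNG is not
// used so that trajectories are bit-identical for a given (seed, replica).
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  int pick(int n) { return (int)(unif() * n) % n; }
};

struct Vec3 { double x, y, z; };

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dist2(const Vec3 &a, const Vec3 &b) {
  double dx = a.x - b.x, dy = a.y - b.y, dz = a.z - b.z;
  return dx * dx + dy * dy + dz * dz;
}

// Rotate point p about axis (unit u) through origin o by angle th (Rodrigues).
static inline Vec3 rotate_about(const Vec3 &p, const Vec3 &o, const Vec3 &u,
                                double ct, double st) {
  Vec3 v = sub(p, o);
  double dotuv = u.x * v.x + u.y * v.y + u.z * v.z;
  Vec3 cr = {u.y * v.z - u.z * v.y, u.z * v.x - u.x * v.z,
             u.x * v.y - u.y * v.x};
  return {o.x + v.x * ct + cr.x * st + u.x * dotuv * (1 - ct),
          o.y + v.y * ct + cr.y * st + u.y * dotuv * (1 - ct),
          o.z + v.z * ct + cr.z * st + u.z * dotuv * (1 - ct)};
}

static inline Vec3 rand_unit(SplitMix &rng) {
  // Marsaglia method
  double a, b, s;
  do {
    a = 2.0 * rng.unif() - 1.0;
    b = 2.0 * rng.unif() - 1.0;
    s = a * a + b * b;
  } while (s >= 1.0 || s == 0.0);
  double r = 2.0 * std::sqrt(1.0 - s);
  return {a * r, b * r, 1.0 - 2.0 * s};
}

// Square-well F-F energy restricted to pairs crossing the moved/static cut.
// phe_of[i] = index into the F-site list if bead i is an F site, else -1.
static double cut_energy(const std::vector<Vec3> &xyz,
                         const std::vector<int> &phe, const NumericMatrix &eps,
                         const std::vector<int> &phe_of,
                         const std::vector<char> &moved, double cutoff2,
                         int lo, int hi) {
  double e = 0.0;
  int nf = (int)phe.size();
  for (int a = 0; a < nf; ++a) {
    int ia = phe[a];
    bool ma = moved[ia] != 0;
    for (int b = a + 1; b < nf; ++b) {
      int ib = phe[b];
      if ((moved[ib] != 0) == ma) continue;  // both sides same partition
      if (dist2(xyz[ia], xyz[ib]) < cutoff2) e -= eps(a, b);
    }
  }
  (void)lo; (void)hi;
  return e;
}

// Full F-F square-well energy of a configuration.
static double total_energy(const std::vector<Vec3> &xyz,
                           const std::vector<int> &phe,
                           const NumericMatrix &eps, double cutoff2) {
  double e = 0.0;
  int nf = (int)phe.size();
  for (int a = 0; a < nf; ++a)
    for (int b = a + 1; b < nf; ++b)
      if (dist2(xyz[phe[a]], xyz[phe[b]]) < cutoff2) e -= eps(a, b);
  return e;
}

// Hard-core overlap check between moved beads [lo, hi] and static beads.
// Bonded neighbours are exempt (they sit at the bond length by construction).
static bool overlaps(const std::vector<Vec3> &xyz, int n, int lo, int hi,
                     double hard2) {
  for (int i = lo; i <= hi; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j >= lo && j <= hi) continue;
      if (std::abs(i - j) < 2) continue;
      if (dist2(xyz[i], xyz[j]) < hard2) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List mc_simulate_cpp(NumericMatrix coords0, IntegerVector phe_idx0,
                     NumericMatrix pair_eps, double hard_diameter,
                     double cohesion_cutoff, int n_sweeps, int record_every,
                     double ns_per_sweep, double seed_lo, double seed_hi) {
  int n = coords0.nrow();
  if (n < 2) stop("need at least 2 beads");
  std::vector<Vec3> xyz(n);
  for (int i = 0; i < n; ++i)
    xyz[i] = {coords0(i, 0), coords0(i, 1), coords0(i, 2)};

  std::vector<int> phe(phe_idx0.begin(), phe_idx0.end());  // 0-based
  std::vector<int> phe_of(n, -1);
  for (size_t k = 0; k < phe.size(); ++k) phe_of[phe[k]] = (int)k;

  double hard2 = hard_diameter * hard_diameter;
  double cutoff2 = cohesion_cutoff * cohesion_cutoff;

  uint64_t seed = ((uint64_t)(uint32_t)seed_hi << 32) | (uint64_t)(uint32_t)seed_lo;
  SplitMix rng(seed);

  double e_curr = total_energy(xyz, phe, pair_eps, cutoff2);
  double e_init = e_curr;
  double delta_sum = 0.0;
  long n_attempt = 0, n_accept = 0;

  int n_frames = n_sweeps / record_every + 1;
  NumericMatrix frames(n_frames, 3 * n);
  NumericVector times(n_frames);
  int fi = 0;
  {
    double cx = 0, cy = 0, cz = 0;
    for (int i = 0; i < n; ++i) { cx += xyz[i].x; cy += xyz[i].y; cz += xyz[i].z; }
    cx /= n; cy /= n; cz /= n;
    for (int i = 0; i < n; ++i) {
      frames(fi, 3 * i) = xyz[i].x - cx;
      frames(fi, 3 * i + 1) = xyz[i].y - cy;
      frames(fi, 3 * i + 2) = xyz[i].z - cz;
    }
  }
  times[fi++] = 0.0;

  std::vector<Vec3> prop(n);
  std::vector<char> moved(n, 0);

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int step = 0; step < n; ++step) {
      ++n_attempt;
      double mtype = rng.unif();
      int lo, hi;            // inclusive moved range
      Vec3 origin, axis;
      double theta;
      if (mtype < 0.45 && n >= 3) {        // pivot
        int p = 1 + rng.pick(n - 2);
        bool tail = rng.unif() < 0.5;
        lo = tail ? p + 1 : 0;
        hi = tail ? n - 1 : p - 1;
        origin = xyz[p];
        axis = rand_unit(rng);
        theta = (2.0 * rng.unif() - 1.0) * M_PI;
      } else if (mtype < 0.85 && n >= 4) { // crankshaft
        int span = 2 + rng.pick(std::min(n - 2, 8));
        int i0 = rng.pick(n - span);
        int j0 = i0 + span;
        lo = i0 + 1; hi = j0 - 1;
        origin = xyz[i0];
        Vec3 d = sub(xyz[j0], xyz[i0]);
        double L = std::sqrt(d.x * d.x + d.y * d.y + d.z * d.z);
        if (L < 1e-12) continue;
        axis = {d.x / L, d.y / L, d.z / L};
        theta = (2.0 * rng.unif() - 1.0) * M_PI;
      } else {                             // end-bead rotation
        bool head = rng.unif() < 0.5;
        lo = hi = head ? 0 : n - 1;
        origin = head ? xyz[1] : xyz[n - 2];
        axis = rand_unit(rng);
        theta = (2.0 * rng.unif() - 1.0) * M_PI;
      }
      double ct = std::cos(theta), st = std::sin(theta);
      for (int i = lo; i <= hi; ++i) moved[i] = 1;

      double e_old = cut_energy(xyz, phe, pair_eps, phe_of, moved, cutoff2,
                                lo, hi);
      for (int i = lo; i <= hi; ++i) prop[i] = xyz[i];
      for (int i = lo; i <= hi; ++i)
        xyz[i] = rotate_about(prop[i], origin, axis, ct, st);

      bool reject = overlaps(xyz, n, lo, hi, hard2);
      double dE = 0.0;
      if (!reject) {
        double e_new = cut_energy(xyz, phe, pair_eps, phe_of, moved, cutoff2,
                                  lo, hi);
        dE = e_new - e_old;
        if (dE > 0.0 && rng.unif() >= std::exp(-dE)) reject = true;
      }
      if (reject) {
        for (int i = lo; i <= hi; ++i) xyz[i] = prop[i];
      } else {
        e_curr += dE;
        delta_sum += dE;
        ++n_accept;
      }
      for (int i = lo; i <= hi; ++i) moved[i] = 0;
    }
    if (sweep % record_every == 0) {
      // record centred at the centroid: absolute position carries no
      // information and small coordinates fit fixed-width PDB output
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < n; ++i) { cx += xyz[i].x; cy += xyz[i].y; cz += xyz[i].z; }
      cx /= n; cy /= n; cz /= n;
      for (int i = 0; i < n; ++i) {
        frames(fi, 3 * i) = xyz[i].x - cx;
        frames(fi, 3 * i + 1) = xyz[i].y - cy;
        frames(fi, 3 * i + 2) = xyz[i].z - cz;
      }
      times[fi++] = sweep * ns_per_sweep;
    }
  }

  double e_final = total_energy(xyz, phe, pair_eps, cutoff2);
  return List::create(
      _["frames"] = frames, _["times_ns"] = times,
      _["energy_initial"] = e_init, _["energy_final"] = e_final,
      _["energy_current"] = e_curr, _["accepted_delta_sum"] = delta_sum,
      _["n_attempt"] = (double)n_attempt, _["n_accept"] = (double)n_accept);
}
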