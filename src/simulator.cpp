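// Photon-stream simulator kernel: Brownian motion of labelled molecules in a
// zero-mode waveguide (cylindrical aperture topped by a short solution
// column), with transient wall adsorption, two-state dark blinking and
// inhomogeneous Poisson photon emission weighted by the evanescent
// detection profile exp(-z / Lambda).
//
// The top of the column is a grand-canonical bath boundary: molecules
// crossing it are removed (the reservoir above the aperture is effectively
// infinite and well mixed, so a molecule that leaves carries no
// correlation back) and fresh molecules enter as a Poisson flux with the
// exact crossing statistics of a uniform bath under one Brownian step
// (rate C A sigma E[Z+], entry depth = U * sigma * sqrt(-2 ln U'), the
// Rayleigh-overshoot law). This keeps the occupancy Poisson at
// concentration x volume, which is what the FCS amplitude 1/N assumes.
//
// The kernel owns its RNG (xoshiro256++ seeded via splitmix64, Box-Muller
// normals): a fit-grade acquisition needs ~1e8 steps, and std::
// distributions are not bit-stable across standard libraries. Identical
// seed + parameters give a bit-identical photon stream.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

namespace {

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
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
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  bool have_cached = false;
  double cached = 0.0;
  inline double norm() {
    if (have_cached) { have_cached = false; return cached; }
    double u1;
    do { u1 = unif(); } while (u1 <= 0.0);
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1));
    const double a = 6.283185307179586476925287 * u2;
    cached = r * std::sin(a);
    have_cached = true;
    return r * std::cos(a);
  }
  inline double expo() {  // mean 1
    double u;
    do { u = unif(); } while (u <= 0.0);
    return -std::log(u);
  }
  inline int pois(double mu) {
    if (mu <= 0.0) return 0;
    if (mu > 50.0) {  // normal approximation, ample for bookkeeping counts
      const double k = std::floor(mu + std::sqrt(mu) * norm() + 0.5);
      return k < 0 ? 0 : static_cast<int>(k);
    }
    double p = std::exp(-mu), cum = p;
    const double u = unif();
    int k = 0;
    while (u > cum && k < 1000) {
      ++k;
      p *= mu / k;
      cum += p;
    }
    return k;
  }
};

struct Photon { double t; int state; };

}  // namespace

using namespace Rcpp;

// [[Rcpp::export(name = ".sim_kernel")]]
List sim_kernel(double radius_nm, double h_ap_nm, double height_nm,
                double lambda_nm, double D_nm2s, double dt_s,
                double conc_per_nm3, double b_free, double b_ads,
                double t_ds, double tau_ds_s, double p_ads,
                double dwell_mean_s, double duration_s, double seed,
                double record_dt_s, bool emit_photons) {
  Rng rng(static_cast<uint64_t>(seed));

  const double R = radius_nm, R2 = R * R, H = height_nm;
  const double area = 3.141592653589793238463 * R2;
  const double sig = std::sqrt(2.0 * D_nm2s * dt_s);
  const double z_cut_emit = 50.0 * lambda_nm;
  const double two_pi = 6.283185307179586476925287;
  const bool blink = t_ds > 0.0;
  const double mean_dark = tau_ds_s;
  const double mean_bright = blink ? tau_ds_s * (1.0 - t_ds) / t_ds : 0.0;
  const double inf = std::numeric_limits<double>::infinity();

  // population bookkeeping (molecules are independent: simulate each from
  // its entry to its exit or the end of the acquisition)
  const double n0_mean = conc_per_nm3 * area * H;
  const int n0 = rng.pois(n0_mean);
  // bath influx: mean downward crossings per step from a uniform half-space
  const double lambda_step = conc_per_nm3 * area * sig * 0.3989422804014327;
  const double n_steps = duration_s / dt_s;
  const int n_in = rng.pois(lambda_step * n_steps);
  const int n_total = n0 + n_in;

  std::vector<Photon> photons;
  std::vector<double> ev_t, ev_dwell, ev_x, ev_y, ev_z;
  std::vector<double> rec_t, rec_x, rec_y, rec_z;
  std::vector<int> rec_mol, rec_kin, rec_bright;

  for (int m = 0; m < n_total; ++m) {
    double t0, x, y, z;
    double rr = R * std::sqrt(rng.unif());
    double th = two_pi * rng.unif();
    x = rr * std::cos(th);
    y = rr * std::sin(th);
    if (m < n0) {  // resident at acquisition start
      t0 = 0.0;
      z = H * rng.unif();
    } else {       // bath entrant: Rayleigh-overshoot entry depth
      t0 = rng.unif() * duration_s;
      double u1;
      do { u1 = rng.unif(); } while (u1 <= 0.0);
      const double w = sig * std::sqrt(-2.0 * std::log(u1));
      double depth = rng.unif() * w;
      if (depth > H) depth = H;
      z = H - depth;
    }
    bool adsorbed = false;
    double release_t = 0.0;
    bool bright = !blink || rng.unif() >= t_ds;
    double t_sw = blink
      ? t0 + rng.expo() * (bright ? mean_bright : mean_dark) : inf;
    double t = t0;
    double next_rec = record_dt_s > 0.0
      ? std::ceil(t0 / record_dt_s) * record_dt_s : inf;
    bool alive = true;

    while (alive && t < duration_s) {
      double h = dt_s;
      if (t + h > duration_s) h = duration_s - t;
      if (adsorbed && t + h > release_t) h = release_t - t;
      if (h <= 0.0) h = dt_s * 1e-9;
      const double t_end = t + h;

      // fraction of this step spent bright (exact switch times)
      double bright_frac = bright ? 1.0 : 0.0;
      if (blink && t_sw <= t_end) {
        double seg = t, bt = 0.0;
        while (t_sw <= t_end) {
          if (bright) bt += t_sw - seg;
          seg = t_sw;
          bright = !bright;
          t_sw += rng.expo() * (bright ? mean_bright : mean_dark);
        }
        if (bright) bt += t_end - seg;
        bright_frac = bt / h;
      }

      // emission over [t, t_end]
      if (emit_photons && bright_frac > 0.0 && z < z_cut_emit) {
        const double rate = (adsorbed ? b_ads : b_free) *
          std::exp(-z / lambda_nm);
        const double mu = rate * h * bright_frac;
        if (mu > 0.0) {
          const int k = rng.pois(mu);
          for (int i = 0; i < k; ++i)
            photons.push_back({t + rng.unif() * h, adsorbed ? 1 : 0});
        }
      }

      // motion / kinetics
      if (adsorbed) {
        if (t_end >= release_t - 1e-15) adsorbed = false;
      } else {
        const double step_sig = (h == dt_s) ? sig
          : std::sqrt(2.0 * D_nm2s * h);
        x += step_sig * rng.norm();
        y += step_sig * rng.norm();
        z += step_sig * rng.norm();
        bool stuck = false;
        if (z < 0.0) {  // floor contact
          if (p_ads > 0.0 && rng.unif() < p_ads) {
            z = 0.0;
            const double r2c = x * x + y * y;
            if (r2c > R2) {
              const double f = R / std::sqrt(r2c);
              x *= f; y *= f;
            }
            stuck = true;
          } else {
            z = -z;
          }
        } else if (z > H) {  // left through the bath boundary
          alive = false;
        }
        if (alive && !stuck) {
          const double r2c = x * x + y * y;
          if (r2c > R2) {  // side-wall contact
            const double r = std::sqrt(r2c);
            if (z <= h_ap_nm && p_ads > 0.0 && rng.unif() < p_ads) {
              const double f = R / r;
              x *= f; y *= f;
              stuck = true;
            } else {
              double rnew = 2.0 * R - r;
              if (rnew < 0.0) rnew = 0.0;
              const double f = (r > 0.0) ? rnew / r : 0.0;
              x *= f; y *= f;
            }
          }
        }
        if (stuck) {
          adsorbed = true;
          const double dwell = rng.expo() * dwell_mean_s;
          release_t = t_end + dwell;
          ev_t.push_back(t_end);
          ev_dwell.push_back(dwell);
          ev_x.push_back(x); ev_y.push_back(y); ev_z.push_back(z);
        }
      }

      t = t_end;
      if (record_dt_s > 0.0 && alive) {
        while (next_rec <= t + 1e-15 && next_rec <= duration_s) {
          rec_t.push_back(next_rec);
          rec_mol.push_back(m + 1);
          rec_x.push_back(x); rec_y.push_back(y); rec_z.push_back(z);
          rec_kin.push_back(adsorbed ? 1 : 0);
          rec_bright.push_back(bright ? 1 : 0);
          next_rec += record_dt_s;
        }
      }
    }
  }

  std::sort(photons.begin(), photons.end(),
            [](const Photon& a, const Photon& b) { return a.t < b.t; });
  const R_xlen_t np = static_cast<R_xlen_t>(photons.size());
  NumericVector pt(np);
  IntegerVector ps(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    pt[i] = photons[i].t;
    ps[i] = photons[i].state;
  }

  List events = List::create(
    _["t"] = wrap(ev_t), _["dwell"] = wrap(ev_dwell),
    _["x"] = wrap(ev_x), _["y"] = wrap(ev_y), _["z"] = wrap(ev_z));
  List paths = List::create(
    _["t"] = wrap(rec_t), _["molecule"] = wrap(rec_mol),
    _["x"] = wrap(rec_x), _["y"] = wrap(rec_y), _["z"] = wrap(rec_z),
    _["adsorbed"] = wrap(rec_kin), _["bright"] = wrap(rec_bright));
  return List::create(_["t"] = pt, _["state"] = ps, _["events"] = events,
                      _["paths"] = paths, _["n_molecules"] = n_total);
}
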