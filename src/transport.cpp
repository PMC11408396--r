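// Woodcock (delta-tracking) photon transport in a voxel grid with local
// energy deposition (kerma approximation: energy transferred to electrons
// is scored where the interaction happens; no electron transport, valid
// below 150 keV where CT electron ranges are sub-voxel).
//
// Units: positions/spacing in mm, energies in keV, mass attenuation tables
// in cm^2/g on a uniform 1 keV energy grid, densities in g/cm^3. Deposits
// are returned as weighted keV per voxel; the caller divides by voxel mass.
//
// Emission sampling happens on the R side under set.seed(); transport
// randomness uses counter-based per-photon streams derived from the
// protocol seed (see Rng below), so simulations are reproducible and
// shared-seed scenario pairs are common-random-number estimates. The
// single-history entry point uses R's RNG directly.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct EnergyGrid {
  double e0, de;
  int n;
  double clamp(double E) const {
    double lo = e0, hi = e0 + de * (n - 1);
    return E < lo ? lo : (E > hi ? hi : E);
  }
  // linear interpolation of a table row laid out contiguously per material
  double interp(const double* tab, double E) const {
    E = clamp(E);
    double u = (E - e0) / de;
    int i = (int)u;
    if (i >= n - 1) return tab[n - 1];
    double f = u - i;
    return tab[i] * (1.0 - f) + tab[i + 1] * f;
  }
};

// Per-photon counter-based RNG (splitmix64): photons with the same stream
// seed and index see identical random sequences regardless of what other
// histories consumed, which makes shared-seed scenario pairs common-random-
// number estimates. A negative stream seed falls back to R's RNG.
struct Rng {
  bool use_r;
  uint64_t s;
  double operator()() {
    if (use_r) return unif_rand();
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

Rng make_rng(double stream_seed, uint64_t index) {
  if (stream_seed < 0) return Rng{true, 0};
  uint64_t s = (uint64_t)stream_seed;
  s = s * 0x9E3779B97F4A7C15ULL + index * 0xBF58476D1CE4E5B9ULL;
  return Rng{false, s};
}

// Klein-Nishina cos(theta) sampling by rejection against the forward-peak
// envelope (the differential cross section is maximal at theta = 0 for all
// energies, where it equals 2 in the units below).
double sample_kn_costheta(double E, Rng& rng) {
  double k = E / 511.0;
  for (int it = 0; it < 10000; ++it) {
    double x = 2.0 * rng() - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - x));         // E'/E
    double f = r * r * (r + 1.0 / r - (1.0 - x * x));
    if (rng() * 2.0 <= f) return x;
  }
  return 1.0;  // unreachable in practice
}

// Thomson-like coherent scatter angle, ~ (1 + cos^2)/2 (form-factor-free)
double sample_rayleigh_costheta(Rng& rng) {
  for (int it = 0; it < 10000; ++it) {
    double x = 2.0 * rng() - 1.0;
    if (rng() * 2.0 <= 1.0 + x * x) return x;
  }
  return 1.0;
}

// rotate unit vector d by polar angle (cost) about itself with uniform
// azimuth; standard scattering-frame rotation
void rotate_direction(double* d, double cost, Rng& rng) {
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * rng();
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double a = std::sqrt(std::max(1e-30, 1.0 - uz * uz));
  double nx, ny, nz;
  if (a > 1e-10) {
    nx = sint * (ux * uz * cphi - uy * sphi) / a + ux * cost;
    ny = sint * (uy * uz * cphi + ux * sphi) / a + uy * cost;
    nz = -sint * cphi * a + uz * cost;
  } else {  // travelling along z
    nx = sint * cphi;
    ny = sint * sphi;
    nz = (uz > 0 ? 1.0 : -1.0) * cost;
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  d[0] = nx / norm; d[1] = ny / norm; d[2] = nz / norm;
}

struct Grid {
  const double* density;   // g/cm^3
  const int* matclass;     // 1-based class index
  int nx, ny, nz;
  double sp[3], org[3];    // mm
  bool inside(const double* p) const {
    return p[0] >= org[0] && p[0] < org[0] + nx * sp[0] &&
           p[1] >= org[1] && p[1] < org[1] + ny * sp[1] &&
           p[2] >= org[2] && p[2] < org[2] + nz * sp[2];
  }
  long voxel(const double* p) const {
    int i = (int)((p[0] - org[0]) / sp[0]);
    int j = (int)((p[1] - org[1]) / sp[1]);
    int k = (int)((p[2] - org[2]) / sp[2]);
    if (i < 0 || i >= nx || j < 0 || j >= ny || k < 0 || k >= nz) return -1;
    return (long)i + (long)nx * ((long)j + (long)ny * (long)k);
  }
  // advance a photon starting outside the box to its entry point;
  // returns false if the ray misses the box
  bool clip_to_box(double* p, const double* d) const {
    if (inside(p)) return true;
    double t0 = 0.0, t1 = 1e30;
    for (int ax = 0; ax < 3; ++ax) {
      double lo = org[ax], hi = org[ax] + sp[ax] * (ax == 0 ? nx : ax == 1 ? ny : nz);
      if (std::fabs(d[ax]) < 1e-12) {
        if (p[ax] < lo || p[ax] >= hi) return false;
      } else {
        double ta = (lo - p[ax]) / d[ax];
        double tb = (hi - p[ax]) / d[ax];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (t0 > t1 || t1 < 0) return false;
    double t = t0 + 1e-6;  // nudge just inside
    p[0] += d[0] * t; p[1] += d[1] * t; p[2] += d[2] * t;
    return inside(p);
  }
};

struct Deposit { long voxel; double kev; };

// transport one photon; deposits weighted keV into dep (per-voxel) and
// optionally logs each deposition event. Returns number of real
// interactions.
int transport_one(double* p, double* d, double E, double w,
                  const Grid& g, const EnergyGrid& eg,
                  const double* mu_rho, const double* f_pe,
                  const double* f_ray, const double* majorant,
                  int nmat, double cutoff,
                  double* dep, std::vector<Deposit>* log, Rng& rng) {
  int n_int = 0;
  if (!std::isfinite(d[0]) || !std::isfinite(d[1]) || !std::isfinite(d[2]))
    stop("non-finite photon direction");
  if (!g.clip_to_box(p, d)) return 0;
  if (E < cutoff) {  // below cutoff on entry: deposit locally
    long v = g.voxel(p);
    if (v >= 0) {
      dep[v] += w * E;
      if (log) log->push_back({v, w * E});
    }
    return 0;
  }
  for (int steps = 0; steps < 1000000; ++steps) {
    double mu_max = eg.interp(majorant, E);            // 1/cm
    double s_cm = -std::log(rng()) / mu_max;
    double s_mm = s_cm * 10.0;
    p[0] += d[0] * s_mm; p[1] += d[1] * s_mm; p[2] += d[2] * s_mm;
    if (!g.inside(p)) return n_int;                    // escaped
    long v = g.voxel(p);
    if (v < 0) return n_int;
    int cls = g.matclass[v] - 1;                       // 0-based
    double mu_real = eg.interp(mu_rho + (size_t)cls * eg.n, E) * g.density[v];
    if (rng() * mu_max > mu_real) continue;            // virtual collision
    ++n_int;
    double u = rng();
    double fpe = eg.interp(f_pe + (size_t)cls * eg.n, E);
    double fra = eg.interp(f_ray + (size_t)cls * eg.n, E);
    if (u < fpe) {                                     // photoelectric
      dep[v] += w * E;
      if (log) log->push_back({v, w * E});
      return n_int;
    } else if (u < fpe + fra) {                        // Rayleigh
      rotate_direction(d, sample_rayleigh_costheta(rng), rng);
    } else {                                           // Compton
      double x = sample_kn_costheta(E, rng);
      double Ep = E / (1.0 + (E / 511.0) * (1.0 - x));
      double de = E - Ep;
      if (de > 0) {
        dep[v] += w * de;
        if (log) log->push_back({v, w * de});
      }
      rotate_direction(d, x, rng);
      E = Ep;
      if (E < cutoff) {                                // terminate locally
        dep[v] += w * E;
        if (log) log->push_back({v, w * E});
        return n_int;
      }
    }
  }
  return n_int;
}

// grid-wide majorant linear attenuation per energy: max over material
// classes of mu/rho times the maximum density present in that class
std::vector<double> build_majorant(const Grid& g, const double* mu_rho,
                                   int nmat, const EnergyGrid& eg) {
  std::vector<double> maxdens(nmat, 0.0);
  long nvox = (long)g.nx * g.ny * g.nz;
  for (long v = 0; v < nvox; ++v) {
    int c = g.matclass[v] - 1;
    if (g.density[v] > maxdens[c]) maxdens[c] = g.density[v];
  }
  std::vector<double> maj(eg.n, 0.0);
  for (int e = 0; e < eg.n; ++e) {
    double m = 0.0;
    for (int c = 0; c < nmat; ++c) {
      double mu = mu_rho[(size_t)c * eg.n + e] * maxdens[c];
      if (mu > m) m = mu;
    }
    maj[e] = std::max(m, 1e-10);
  }
  return maj;
}

Grid make_grid(NumericVector density, IntegerVector matclass,
               IntegerVector dims, NumericVector spacing,
               NumericVector origin) {
  Grid g;
  g.density = REAL(density);
  g.matclass = INTEGER(matclass);
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  for (int i = 0; i < 3; ++i) { g.sp[i] = spacing[i]; g.org[i] = origin[i]; }
  return g;
}

}  // namespace

// [[Rcpp::export]]
List cpp_transport_batch(NumericMatrix pos, NumericMatrix dir,
                         NumericVector energy, NumericVector weight,
                         IntegerVector tag, int ntags,
                         NumericVector density, IntegerVector matclass,
                         IntegerVector dims, NumericVector spacing,
                         NumericVector origin,
                         NumericMatrix mu_rho, NumericMatrix f_pe,
                         NumericMatrix f_ray, double e0, double de,
                         double cutoff, double stream_seed,
                         double index_offset) {
  RNGScope scope;
  Grid g = make_grid(density, matclass, dims, spacing, origin);
  int nmat = mu_rho.ncol();
  EnergyGrid eg{e0, de, mu_rho.nrow()};
  // column-major matrices: column c is material c's table, contiguous
  std::vector<double> maj = build_majorant(g, REAL(mu_rho), nmat, eg);
  long nvox = (long)g.nx * g.ny * g.nz;
  List out(ntags);
  std::vector<double*> dep(ntags);
  for (int t = 0; t < ntags; ++t) {
    NumericVector d(nvox);
    out[t] = d;
    dep[t] = REAL(d);
  }
  int n = pos.nrow();
  for (int i = 0; i < n; ++i) {
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double dvec[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};
    int t = tag[i];
    if (t < 0 || t >= ntags) stop("tag out of range");
    Rng rng = make_rng(stream_seed, (uint64_t)(index_offset + i));
    transport_one(p, dvec, energy[i], weight[i], g, eg,
                  REAL(mu_rho), REAL(f_pe), REAL(f_ray), maj.data(),
                  nmat, cutoff, dep[t], nullptr, rng);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_transport_one(NumericVector pos, NumericVector dir, double energy,
                       double weight,
                       NumericVector density, IntegerVector matclass,
                       IntegerVector dims, NumericVector spacing,
                       NumericVector origin,
                       NumericMatrix mu_rho, NumericMatrix f_pe,
                       NumericMatrix f_ray, double e0, double de,
                       double cutoff) {
  RNGScope scope;
  Grid g = make_grid(density, matclass, dims, spacing, origin);
  int nmat = mu_rho.ncol();
  EnergyGrid eg{e0, de, mu_rho.nrow()};
  std::vector<double> maj = build_majorant(g, REAL(mu_rho), nmat, eg);
  long nvox = (long)g.nx * g.ny * g.nz;
  std::vector<double> dep(nvox, 0.0);
  std::vector<Deposit> log;
  double p[3] = {pos[0], pos[1], pos[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  Rng rng{true, 0};
  int n_int = transport_one(p, d, energy, weight, g, eg,
                            REAL(mu_rho), REAL(f_pe), REAL(f_ray),
                            maj.data(), nmat, cutoff, dep.data(), &log, rng);
  int m = log.size();
  IntegerVector vox(m);
  NumericVector kev(m);
  for (int i = 0; i < m; ++i) {
    vox[i] = (int)log[i].voxel + 1;  // 1-based for R
    kev[i] = log[i].kev;
  }
  return List::create(_["voxel"] = vox, _["energy_kev"] = kev,
                      _["n_interactions"] = n_int);
}

// [[Rcpp::export]]
List cpp_sample_compton(int n, double energy) {
  RNGScope scope;
  Rng rng{true, 0};
  NumericVector cost(n), eprime(n);
  for (int i = 0; i < n; ++i) {
    double x = sample_kn_costheta(energy, rng);
    cost[i] = x;
    eprime[i] = energy / (1.0 + (energy / 511.0) * (1.0 - x));
  }
  return List::create(_["cos_theta"] = cost, _["energy_kev"] = eprime);
}
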