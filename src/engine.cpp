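// Langevin-dynamics core for the heteromorphic chromatin polymer model.
//
// Integrates m d2r/dt2 = -grad U - gamma v + sqrt(2 kBT gamma) eta with the
// BAOAB splitting (reduces exactly to velocity Verlet when gamma = 0, which
// is the NVE validation mode). Positions are kept unwrapped; the minimum
// image convention is applied to nonbonded pair vectors, so bonds and angles
// are always evaluated on real-space coordinates and trajectories can be
// used directly for centre-of-mass (FISH) measurements.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t rotl64(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

// xoshiro256++ seeded via splitmix64: bit-reproducible across platforms,
// unlike std:: distributions.
struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  uint64_t next() {
    const uint64_t r = rotl64(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl64(s[3], 45);
    return r;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller, cached spare
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

static const double WCA_CUT = std::pow(2.0, 1.0 / 6.0);

struct System {
  int n;
  std::vector<double> x, y, z;      // unwrapped positions
  std::vector<double> vx, vy, vz;
  std::vector<double> fx, fy, fz;
  double box[3];
  bool periodic;
  std::vector<int> type;
  // nonbonded
  int nb_mode;                      // 0 none, 1 soft, 2 eps-matrix (WCA/shifted LJ)
  NumericMatrix eps;
  double rc_attr, lj_norm, lj_shift;
  double soft_a;
  // walls (used only when !periodic)
  bool walls;
  double wall_a, wall_cut;
  // bonds
  bool bonded_wca;                  // WCA on FENE pairs when nonbonded is off
  IntegerMatrix fene_b; double fene_k, fene_r0;
  IntegerMatrix harm_b; NumericVector harm_k, harm_r0;
  IntegerMatrix ang;    double ang_k;

  inline void minimg(double& dx, double& dy, double& dz) const {
    if (!periodic) return;
    dx -= box[0] * std::nearbyint(dx / box[0]);
    dy -= box[1] * std::nearbyint(dy / box[1]);
    dz -= box[2] * std::nearbyint(dz / box[2]);
  }

  // pair force magnitude (-dU/dr) and energy for separation r between types ti, tj
  inline void pair_fu(int ti, int tj, double r, double& f, double& u) const {
    f = 0.0; u = 0.0;
    if (nb_mode == 1) {
      if (r < WCA_CUT) {
        double w = M_PI / WCA_CUT;
        u = soft_a * (1.0 + std::cos(w * r));
        f = soft_a * w * std::sin(w * r);
      }
      return;
    }
    double e = eps(ti, tj);
    if (e > 0.0) {
      if (r < rc_attr) {
        double ri = 1.0 / r, ri6 = std::pow(ri, 6);
        double pref = 4.0 * e * lj_norm;
        u = pref * (ri6 * ri6 - ri6 - lj_shift);
        f = pref * (12.0 * ri6 * ri6 - 6.0 * ri6) * ri;
      }
    } else {
      if (r < WCA_CUT) {
        double ri = 1.0 / r, ri6 = std::pow(ri, 6);
        u = 4.0 * (ri6 * ri6 - ri6 + 0.25);
        f = 4.0 * (12.0 * ri6 * ri6 - 6.0 * ri6) * ri;
      }
    }
  }

  double nb_cutoff() const {
    if (nb_mode == 0) return 0.0;
    if (nb_mode == 1) return WCA_CUT;
    // any attractive pair present?
    for (int i = 0; i < eps.nrow(); i++)
      for (int j = 0; j < eps.ncol(); j++)
        if (eps(i, j) > 0.0) return rc_attr;
    return WCA_CUT;
  }
};

static void accumulate_pair(System& S, int i, int j, double& pot) {
  double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
  S.minimg(dx, dy, dz);
  double r2 = dx * dx + dy * dy + dz * dz;
  double cut = (S.nb_mode == 2) ? S.rc_attr : WCA_CUT;
  if (r2 >= cut * cut || r2 < 1e-24) return;
  double r = std::sqrt(r2);
  double f, u;
  S.pair_fu(S.type[i], S.type[j], r, f, u);
  if (f != 0.0 || u != 0.0) {
    pot += u;
    double fr = f / r;
    S.fx[i] += fr * dx; S.fy[i] += fr * dy; S.fz[i] += fr * dz;
    S.fx[j] -= fr * dx; S.fy[j] -= fr * dy; S.fz[j] -= fr * dz;
  }
}

// Nonbonded via cell list when the periodic box admits >= 3 cells per
// dimension at the largest cutoff; otherwise all pairs with minimum image.
static double nonbonded(System& S) {
  double pot = 0.0;
  if (S.nb_mode == 0) return 0.0;
  double cut = S.nb_cutoff();
  int nc[3];
  bool use_cells = S.periodic;
  for (int d = 0; d < 3; d++) {
    nc[d] = (int)std::floor(S.box[d] / cut);
    if (nc[d] < 3) use_cells = false;
  }
  if (!use_cells) {
    for (int i = 0; i < S.n; i++)
      for (int j = i + 1; j < S.n; j++)
        accumulate_pair(S, i, j, pot);
    return pot;
  }
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(S.n, -1), cellof(S.n);
  for (int i = 0; i < S.n; i++) {
    double w[3] = { S.x[i], S.y[i], S.z[i] };
    int c[3];
    for (int d = 0; d < 3; d++) {
      double s = w[d] / S.box[d];
      s -= std::floor(s);                 // [0,1)
      c[d] = (int)(s * nc[d]);
      if (c[d] >= nc[d]) c[d] = nc[d] - 1;
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cellof[i] = ci;
    nxt[i] = head[ci];
    head[ci] = i;
  }
  // half list of neighbour cell offsets (13) + same cell
  static const int off[13][3] = {
    {1,0,0},{-1,1,0},{0,1,0},{1,1,0},
    {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
    {-1,1,1},{0,1,1},{1,1,1}};
  for (int cz = 0; cz < nc[2]; cz++)
    for (int cy = 0; cy < nc[1]; cy++)
      for (int cx = 0; cx < nc[0]; cx++) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        for (int i = head[ci]; i >= 0; i = nxt[i])
          for (int j = nxt[i]; j >= 0; j = nxt[j])
            accumulate_pair(S, i, j, pot);
        for (int k = 0; k < 13; k++) {
          int ax = (cx + off[k][0] + nc[0]) % nc[0];
          int ay = (cy + off[k][1] + nc[1]) % nc[1];
          int az = (cz + off[k][2] + nc[2]) % nc[2];
          int cj = (az * nc[1] + ay) * nc[0] + ax;
          if (cj == ci) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i])
            for (int j = head[cj]; j >= 0; j = nxt[j])
              accumulate_pair(S, i, j, pot);
        }
      }
  return pot;
}

static double bonded(System& S, int step_for_error) {
  double pot = 0.0;
  // FENE backbone
  for (int b = 0; b < S.fene_b.nrow(); b++) {
    int i = S.fene_b(b, 0), j = S.fene_b(b, 1);
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    double q = 1.0 - r2 / (S.fene_r0 * S.fene_r0);
    if (q <= 0.0 || !std::isfinite(r2))
      stop("FENE bond blow-up (r >= R0) between beads %d and %d at step %d; "
           "reduce the timestep", i + 1, j + 1, step_for_error);
    pot += -(S.fene_k * S.fene_r0 * S.fene_r0 / 2.0) * std::log(q);
    double fr = -S.fene_k / q;  // (-dU/dr)/r
    if (S.bonded_wca && S.nb_mode == 0) {
      double r = std::sqrt(r2);
      if (r < WCA_CUT && r > 1e-12) {
        double ri = 1.0 / r, ri6 = std::pow(ri, 6);
        pot += 4.0 * (ri6 * ri6 - ri6 + 0.25);
        fr += 4.0 * (12.0 * ri6 * ri6 - 6.0 * ri6) * ri / r;
      }
    }
    S.fx[i] += fr * dx; S.fy[i] += fr * dy; S.fz[i] += fr * dz;
    S.fx[j] -= fr * dx; S.fy[j] -= fr * dy; S.fz[j] -= fr * dz;
  }
  // harmonic bonds (crumple springs, extruder springs, rosette-stage backbone)
  for (int b = 0; b < S.harm_b.nrow(); b++) {
    int i = S.harm_b(b, 0), j = S.harm_b(b, 1);
    double k = S.harm_k[b], r0 = S.harm_r0[b];
    double dx = S.x[i] - S.x[j], dy = S.y[i] - S.y[j], dz = S.z[i] - S.z[j];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    pot += k * (r - r0) * (r - r0);
    double fr = -2.0 * k * (r - r0) / r;
    S.fx[i] += fr * dx; S.fy[i] += fr * dy; S.fz[i] += fr * dz;
    S.fx[j] -= fr * dx; S.fy[j] -= fr * dy; S.fz[j] -= fr * dz;
  }
  // Kratky-Porod angles: U = k (1 - cos theta)
  for (int a = 0; a < S.ang.nrow(); a++) {
    int i = S.ang(a, 0), j = S.ang(a, 1), k = S.ang(a, 2);
    double r1x = S.x[j] - S.x[i], r1y = S.y[j] - S.y[i], r1z = S.z[j] - S.z[i];
    double r2x = S.x[k] - S.x[j], r2y = S.y[k] - S.y[j], r2z = S.z[k] - S.z[j];
    double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
    double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
    if (n1 < 1e-12 || n2 < 1e-12) continue;
    double inv12 = 1.0 / (n1 * n2);
    double c = (r1x * r2x + r1y * r2y + r1z * r2z) * inv12;
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    pot += S.ang_k * (1.0 - c);
    // d cos/d r1 and d cos/d r2
    double g1x = r2x * inv12 - c * r1x / (n1 * n1);
    double g1y = r2y * inv12 - c * r1y / (n1 * n1);
    double g1z = r2z * inv12 - c * r1z / (n1 * n1);
    double g2x = r1x * inv12 - c * r2x / (n2 * n2);
    double g2y = r1y * inv12 - c * r2y / (n2 * n2);
    double g2z = r1z * inv12 - c * r2z / (n2 * n2);
    // with r1 = rj - ri, r2 = rk - rj: F_i = -k g1, F_k = +k g2, F_j = -(F_i + F_k)
    double fix = -S.ang_k * g1x, fiy = -S.ang_k * g1y, fiz = -S.ang_k * g1z;
    double fkx =  S.ang_k * g2x, fky =  S.ang_k * g2y, fkz =  S.ang_k * g2z;
    S.fx[i] += fix; S.fy[i] += fiy; S.fz[i] += fiz;
    S.fx[k] += fkx; S.fy[k] += fky; S.fz[k] += fkz;
    S.fx[j] -= fix + fkx; S.fy[j] -= fiy + fky; S.fz[j] -= fiz + fkz;
  }
  return pot;
}

// soft repulsive walls on all six faces of the box (centred at the origin)
static double wall_term(System& S) {
  if (S.periodic || !S.walls) return 0.0;
  double pot = 0.0;
  double wc = S.wall_cut, w = M_PI / wc;
  double* pos[3] = { S.x.data(), S.y.data(), S.z.data() };
  double* frc[3] = { S.fx.data(), S.fy.data(), S.fz.data() };
  for (int d = 0; d < 3; d++) {
    double half = S.box[d] / 2.0;
    for (int i = 0; i < S.n; i++) {
      double lo = pos[d][i] + half;   // distance to lower face
      double hi = half - pos[d][i];   // distance to upper face
      if (lo < wc) {
        double q = lo < 0 ? 0 : lo;
        pot += S.wall_a * (1.0 + std::cos(w * q));
        frc[d][i] += S.wall_a * w * std::sin(w * q) + (lo < 0 ? S.wall_a * w : 0);
      }
      if (hi < wc) {
        double q = hi < 0 ? 0 : hi;
        pot += S.wall_a * (1.0 + std::cos(w * q));
        frc[d][i] -= S.wall_a * w * std::sin(w * q) + (hi < 0 ? S.wall_a * w : 0);
      }
    }
  }
  return pot;
}

static double forces(System& S, int step) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  double pot = bonded(S, step);
  pot += nonbonded(S);
  pot += wall_term(S);
  return pot;
}

static System make_system(NumericMatrix pos, NumericMatrix vel,
                          NumericVector box, bool periodic,
                          IntegerVector type, NumericMatrix eps,
                          double rc_attr, double lj_norm,
                          int nb_mode, double soft_a,
                          bool walls, double wall_a,
                          bool bonded_wca,
                          IntegerMatrix fene_bonds, double fene_k, double fene_r0,
                          IntegerMatrix harm_bonds, NumericVector harm_k,
                          NumericVector harm_r0,
                          IntegerMatrix angles, double angle_k) {
  System S;
  S.n = pos.nrow();
  if (vel.nrow() != S.n) stop("pos/vel size mismatch");
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  for (int i = 0; i < S.n; i++) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
  }
  for (int d = 0; d < 3; d++) S.box[d] = box[d];
  S.periodic = periodic;
  S.type = std::vector<int>(type.begin(), type.end());
  S.nb_mode = nb_mode;
  S.eps = eps;
  S.rc_attr = rc_attr;
  S.lj_norm = lj_norm;
  S.lj_shift = std::pow(1.0 / rc_attr, 12) - std::pow(1.0 / rc_attr, 6);
  S.soft_a = soft_a;
  S.walls = walls; S.wall_a = wall_a; S.wall_cut = WCA_CUT;
  S.bonded_wca = bonded_wca;
  S.fene_b = fene_bonds; S.fene_k = fene_k; S.fene_r0 = fene_r0;
  S.harm_b = harm_bonds; S.harm_k = harm_k; S.harm_r0 = harm_r0;
  S.ang = angles; S.ang_k = angle_k;
  return S;
}

// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel,
                NumericVector box, bool periodic,
                IntegerVector type, NumericMatrix eps,
                double rc_attr, double lj_norm,
                int nb_mode, double soft_a,
                bool walls, double wall_a, bool bonded_wca,
                IntegerMatrix fene_bonds, double fene_k, double fene_r0,
                IntegerMatrix harm_bonds, NumericVector harm_k,
                NumericVector harm_r0,
                IntegerMatrix angles, double angle_k,
                int nsteps, double dt, double mass, double gamma,
                double temp, bool thermostat, double seed) {
  System S = make_system(pos, vel, box, periodic, type, eps, rc_attr, lj_norm,
                         nb_mode, soft_a, walls, wall_a, bonded_wca,
                         fene_bonds, fene_k, fene_r0,
                         harm_bonds, harm_k, harm_r0, angles, angle_k);
  Rng rng((uint64_t)seed);
  double c1 = 1.0, c2 = 0.0;
  if (thermostat && gamma > 0.0) {
    c1 = std::exp(-gamma * dt / mass);
    c2 = std::sqrt((1.0 - c1 * c1) * temp / mass);
  }
  double hdtm = 0.5 * dt / mass, hdt = 0.5 * dt;
  forces(S, 0);
  for (int step = 1; step <= nsteps; step++) {
    for (int i = 0; i < S.n; i++) {         // B
      S.vx[i] += hdtm * S.fx[i];
      S.vy[i] += hdtm * S.fy[i];
      S.vz[i] += hdtm * S.fz[i];
    }
    for (int i = 0; i < S.n; i++) {         // A
      S.x[i] += hdt * S.vx[i];
      S.y[i] += hdt * S.vy[i];
      S.z[i] += hdt * S.vz[i];
    }
    if (thermostat && gamma > 0.0) {        // O
      for (int i = 0; i < S.n; i++) {
        S.vx[i] = c1 * S.vx[i] + c2 * rng.gauss();
        S.vy[i] = c1 * S.vy[i] + c2 * rng.gauss();
        S.vz[i] = c1 * S.vz[i] + c2 * rng.gauss();
      }
    }
    for (int i = 0; i < S.n; i++) {         // A
      S.x[i] += hdt * S.vx[i];
      S.y[i] += hdt * S.vy[i];
      S.z[i] += hdt * S.vz[i];
    }
    forces(S, step);                        // B
    for (int i = 0; i < S.n; i++) {
      S.vx[i] += hdtm * S.fx[i];
      S.vy[i] += hdtm * S.fy[i];
      S.vz[i] += hdtm * S.fz[i];
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix opos(S.n, 3), ovel(S.n, 3);
  for (int i = 0; i < S.n; i++) {
    opos(i, 0) = S.x[i]; opos(i, 1) = S.y[i]; opos(i, 2) = S.z[i];
    ovel(i, 0) = S.vx[i]; ovel(i, 1) = S.vy[i]; ovel(i, 2) = S.vz[i];
    if (!std::isfinite(S.x[i]) || !std::isfinite(S.vx[i]))
      stop("non-finite coordinate for bead %d after integration", i + 1);
  }
  return List::create(_["pos"] = opos, _["vel"] = ovel);
}

// [[Rcpp::export]]
List md_energy_cpp(NumericMatrix pos, NumericMatrix vel,
                   NumericVector box, bool periodic,
                   IntegerVector type, NumericMatrix eps,
                   double rc_attr, double lj_norm,
                   int nb_mode, double soft_a,
                   bool walls, double wall_a, bool bonded_wca,
                   IntegerMatrix fene_bonds, double fene_k, double fene_r0,
                   IntegerMatrix harm_bonds, NumericVector harm_k,
                   NumericVector harm_r0,
                   IntegerMatrix angles, double angle_k, double mass) {
  System S = make_system(pos, vel, box, periodic, type, eps, rc_attr, lj_norm,
                         nb_mode, soft_a, walls, wall_a, bonded_wca,
                         fene_bonds, fene_k, fene_r0,
                         harm_bonds, harm_k, harm_r0, angles, angle_k);
  double pot = forces(S, 0);
  double kin = 0.0;
  for (int i = 0; i < S.n; i++)
    kin += 0.5 * mass * (S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i]);
  return List::create(_["kinetic"] = kin, _["potential"] = pot,
                      _["total"] = kin + pot);
}
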