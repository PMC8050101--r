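// Overdamped Brownian dynamics of bead-spring semiflexible filaments in a
// sphere. Units: length µm, force pN, energy pN·µm, time s.
//
// The same inline kernels back both the exported per-component force/energy
// functions (brute-force pair search, used by tests and finite-difference
// checks) and the production integrator loop (Verlet pair list).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64. The integrator owns its stream so a
// run is bit-reproducible from (params, seed) regardless of R's RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
    init_zig();
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // Ziggurat normal sampler (Marsaglia & Tsang, 128 layers); tables built
  // once per stream. Validated against closed-form moments in the test
  // suite via the diffusion and equipartition checks.
  uint32_t kn[128];
  double wn[128], fn[128];
  void init_zig() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
  inline int32_t next32() { return (int32_t)(next() >> 32); }
  inline double norm() {
    for (;;) {
      int32_t hz = next32();
      uint32_t iz = (uint32_t)hz & 127u;
      uint32_t ahz = (uint32_t)(hz < 0 ? -(int64_t)hz : hz);
      if (ahz < kn[iz]) return hz * wn[iz];
      // tail / wedge rejection
      if (iz == 0) {
        double xx, yy;
        do {
          xx = -std::log(unif()) * 0.29047645161474317;  // 1/3.442619855899
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return hz > 0 ? 3.442619855899 + xx : -3.442619855899 - xx;
      }
      double x = hz * wn[iz];
      if (fn[iz] + unif() * (fn[iz - 1] - fn[iz]) < std::exp(-0.5 * x * x))
        return x;
    }
  }
};

// ---------------------------------------------------------------------------
// Force kernels. Positions as flat arrays x,y,z. Forces accumulated in-place.
// ---------------------------------------------------------------------------

struct Params {
  double R, l0, kT, gamma, k_spring, kappa_bend;
  double k_atr, r_c, sigma_c, k_rep;
  bool attract;
  double k_b, k_ba, d_b, trap_k;
  double dt, poly_rate, poly_angle_sd;
  double spb;  // subunits per bead
};

static Params read_params(const List& p) {
  Params q;
  q.R = p["R"]; q.l0 = p["l0"]; q.kT = p["kT"]; q.gamma = p["gamma"];
  q.k_spring = p["k_spring"]; q.kappa_bend = p["kappa_bend"];
  q.k_atr = p["k_atr"]; q.r_c = p["r_c"]; q.sigma_c = p["sigma_c"];
  q.k_rep = p["k_rep"];
  q.attract = as<bool>(p["attract"]);
  q.k_b = p["k_b"]; q.k_ba = p["k_ba"]; q.d_b = p["d_b"];
  q.trap_k = p["trap_k"];
  q.dt = p["dt"]; q.poly_rate = p["poly_rate"];
  q.poly_angle_sd = p["poly_angle_sd"]; q.spb = p["spb"];
  return q;
}

// Hookean backbone spring between bonded beads a-b.
static inline void spring_pair(const double* x, const double* y, const double* z,
                               int a, int b, double k, double l0,
                               double* fx, double* fy, double* fz) {
  double dx = x[b] - x[a], dy = y[b] - y[a], dz = z[b] - z[a];
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (d < 1e-9) return;  // degenerate bond: force capped to zero
  double f = k * (d - l0) / d;  // >0 pulls a toward b
  fx[a] += f * dx; fy[a] += f * dy; fz[a] += f * dz;
  fx[b] -= f * dx; fy[b] -= f * dy; fz[b] -= f * dz;
}

// Discrete worm-like-chain bend at triplet (a, b, c): E = kappa * (1 - cos th).
static inline void bend_triplet(const double* x, const double* y, const double* z,
                                int a, int b, int c, double kappa,
                                double* fx, double* fy, double* fz) {
  double ax = x[b] - x[a], ay = y[b] - y[a], az = z[b] - z[a];
  double bx = x[c] - x[b], by = y[c] - y[b], bz = z[c] - z[b];
  double na2 = ax * ax + ay * ay + az * az;
  double nb2 = bx * bx + by * by + bz * bz;
  if (na2 < 1e-18 || nb2 < 1e-18) return;
  double na = std::sqrt(na2), nb = std::sqrt(nb2);
  double inab = 1.0 / (na * nb);
  double ct = (ax * bx + ay * by + az * bz) * inab;
  // d(cos)/da and d(cos)/db
  double dca_x = bx * inab - ct * ax / na2;
  double dca_y = by * inab - ct * ay / na2;
  double dca_z = bz * inab - ct * az / na2;
  double dcb_x = ax * inab - ct * bx / nb2;
  double dcb_y = ay * inab - ct * by / nb2;
  double dcb_z = az * inab - ct * bz / nb2;
  // F = -dE/dx = +kappa * d(cos)/dx
  fx[a] += kappa * (-dca_x); fy[a] += kappa * (-dca_y); fz[a] += kappa * (-dca_z);
  fx[b] += kappa * (dca_x - dcb_x);
  fy[b] += kappa * (dca_y - dcb_y);
  fz[b] += kappa * (dca_z - dcb_z);
  fx[c] += kappa * dcb_x; fy[c] += kappa * dcb_y; fz[c] += kappa * dcb_z;
}

// Cross-filament pair: harmonic attraction anchored at contact sigma_c,
// active on [sigma_c, r_c); harmonic excluded-volume repulsion below sigma_c.
static inline void crosslink_pair(const double* x, const double* y, const double* z,
                                  int i, int j, const Params& p,
                                  double* fx, double* fy, double* fz) {
  double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 >= p.r_c * p.r_c) return;
  double d = std::sqrt(d2);
  if (d < 1e-9) return;
  double f;  // along +d pulls i toward j
  if (d >= p.sigma_c) f = p.k_atr * (d - p.sigma_c) / d;
  else f = -p.k_rep * (p.sigma_c - d) / d;
  fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
  fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
}

static inline double crosslink_pair_energy(double d, const Params& p) {
  if (d >= p.r_c) return 0.0;
  double off = 0.5 * p.k_atr * (p.r_c - p.sigma_c) * (p.r_c - p.sigma_c);
  if (d >= p.sigma_c) return 0.5 * p.k_atr * (d - p.sigma_c) * (d - p.sigma_c) - off;
  return 0.5 * p.k_rep * (p.sigma_c - d) * (p.sigma_c - d) - off;
}

// Radial wall spring; optional harmonic surface attraction well on
// (R - d_b, R]; optional central harmonic trap (validation harness).
static inline void boundary_bead(const double* x, const double* y, const double* z,
                                 int i, const Params& p,
                                 double* fx, double* fy, double* fz) {
  double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
  if (p.trap_k > 0.0) {
    fx[i] -= p.trap_k * x[i]; fy[i] -= p.trap_k * y[i]; fz[i] -= p.trap_k * z[i];
  }
  double inner = p.attract ? (p.R - p.d_b) : p.R;
  if (r2 <= inner * inner) return;  // interior: no radial force
  if (r2 < 1e-18) return;
  double r = std::sqrt(r2);
  double fr = 0.0;  // radial force, + = outward
  if (r > p.R) fr = -p.k_b * (r - p.R);
  else if (p.attract && r > p.R - p.d_b) fr = p.k_ba * (p.R - r);
  if (fr != 0.0) {
    double s = fr / r;
    fx[i] += s * x[i]; fy[i] += s * y[i]; fz[i] += s * z[i];
  }
}

static inline double boundary_bead_energy(double r, const Params& p) {
  double e = 0.0;
  if (p.trap_k > 0.0) e += 0.5 * p.trap_k * r * r;
  if (r > p.R) e += 0.5 * p.k_b * (r - p.R) * (r - p.R);
  else if (p.attract && r > p.R - p.d_b)
    e += 0.5 * p.k_ba * (p.R - r) * (p.R - r) - 0.5 * p.k_ba * p.d_b * p.d_b;
  return e;
}

// ---------------------------------------------------------------------------
// Exported per-component forces / energies (brute force; test surface).
// fil: integer filament id per bead; beads of a filament contiguous, in chain
// order, barbed end last.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix spring_forces_cpp(NumericMatrix pos, IntegerVector fil,
                                double k_spring, double l0) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> x(n), y(n), z(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  for (int i = 0; i + 1 < n; i++)
    if (fil[i] == fil[i + 1])
      spring_pair(x.data(), y.data(), z.data(), i, i + 1, k_spring, l0,
                  fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double spring_energy_cpp(NumericMatrix pos, IntegerVector fil,
                         double k_spring, double l0) {
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i + 1 < n; i++) {
    if (fil[i] != fil[i + 1]) continue;
    double dx = pos(i + 1, 0) - pos(i, 0);
    double dy = pos(i + 1, 1) - pos(i, 1);
    double dz = pos(i + 1, 2) - pos(i, 2);
    double d = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += 0.5 * k_spring * (d - l0) * (d - l0);
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix bending_forces_cpp(NumericMatrix pos, IntegerVector fil,
                                 double kappa) {
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> x(n), y(n), z(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  for (int i = 1; i + 1 < n; i++)
    if (fil[i - 1] == fil[i] && fil[i] == fil[i + 1])
      bend_triplet(x.data(), y.data(), z.data(), i - 1, i, i + 1, kappa,
                   fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double bending_energy_cpp(NumericMatrix pos, IntegerVector fil, double kappa) {
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 1; i + 1 < n; i++) {
    if (!(fil[i - 1] == fil[i] && fil[i] == fil[i + 1])) continue;
    double ax = pos(i, 0) - pos(i - 1, 0), ay = pos(i, 1) - pos(i - 1, 1),
           az = pos(i, 2) - pos(i - 1, 2);
    double bx = pos(i + 1, 0) - pos(i, 0), by = pos(i + 1, 1) - pos(i, 1),
           bz = pos(i + 1, 2) - pos(i, 2);
    double na = std::sqrt(ax * ax + ay * ay + az * az);
    double nb = std::sqrt(bx * bx + by * by + bz * bz);
    if (na < 1e-9 || nb < 1e-9) continue;
    double ct = (ax * bx + ay * by + az * bz) / (na * nb);
    e += kappa * (1.0 - ct);
  }
  return e;
}

// [[Rcpp::export]]
NumericMatrix crosslink_forces_cpp(NumericMatrix pos, IntegerVector fil,
                                   List par) {
  Params p = read_params(par);
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> x(n), y(n), z(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++)
      if (fil[i] != fil[j])
        crosslink_pair(x.data(), y.data(), z.data(), i, j, p,
                       fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double crosslink_energy_cpp(NumericMatrix pos, IntegerVector fil, List par) {
  Params p = read_params(par);
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      if (fil[i] == fil[j]) continue;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1),
             dz = pos(j, 2) - pos(i, 2);
      e += crosslink_pair_energy(std::sqrt(dx * dx + dy * dy + dz * dz), p);
    }
  return e;
}

// [[Rcpp::export]]
NumericMatrix boundary_forces_cpp(NumericMatrix pos, List par) {
  Params p = read_params(par);
  int n = pos.nrow();
  NumericMatrix F(n, 3);
  std::vector<double> x(n), y(n), z(n), fx(n, 0), fy(n, 0), fz(n, 0);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  for (int i = 0; i < n; i++)
    boundary_bead(x.data(), y.data(), z.data(), i, p, fx.data(), fy.data(), fz.data());
  for (int i = 0; i < n; i++) { F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i]; }
  return F;
}

// [[Rcpp::export]]
double boundary_energy_cpp(NumericMatrix pos, List par) {
  Params p = read_params(par);
  int n = pos.nrow();
  double e = 0.0;
  for (int i = 0; i < n; i++) {
    double r = std::sqrt(pos(i, 0) * pos(i, 0) + pos(i, 1) * pos(i, 1) +
                         pos(i, 2) * pos(i, 2));
    e += boundary_bead_energy(r, p);
  }
  return e;
}

// ---------------------------------------------------------------------------
// Integrator. Euler-Maruyama: x += (F/gamma) dt + sqrt(2 kT dt / gamma) xi.
// Verlet pair list for cross-filament interactions; polymerization adds beads
// at the barbed (tail) end with per-step probability poly_rate * dt.
// ---------------------------------------------------------------------------

struct CellGrid {
  double x0, y0, z0, cs;
  int nx, ny, nz;
  std::vector<int> head, nxt;
  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, int n, double cell) {
    double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0],
           zmin = z[0], zmax = z[0];
    for (int i = 1; i < n; i++) {
      xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
      ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
      zmin = std::min(zmin, z[i]); zmax = std::max(zmax, z[i]);
    }
    cs = cell;
    x0 = xmin - 1e-9; y0 = ymin - 1e-9; z0 = zmin - 1e-9;
    nx = std::max(1, std::min(96, (int)((xmax - x0) / cs) + 1));
    ny = std::max(1, std::min(96, (int)((ymax - y0) / cs) + 1));
    nz = std::max(1, std::min(96, (int)((zmax - z0) / cs) + 1));
    // if capped, enlarge cell size so the grid still covers the extent
    cs = std::max(cs, std::max((xmax - x0) / nx,
                               std::max((ymax - y0) / ny, (zmax - z0) / nz)) + 1e-9);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; i++) {
      int cxi = std::min(nx - 1, (int)((x[i] - x0) / cs));
      int cyi = std::min(ny - 1, (int)((y[i] - y0) / cs));
      int czi = std::min(nz - 1, (int)((z[i] - z0) / cs));
      int c = (czi * ny + cyi) * nx + cxi;
      nxt[i] = head[c]; head[c] = i;
    }
  }
};

// [[Rcpp::export]]
List bd_run_cpp(NumericMatrix pos0, IntegerVector fil0, double pool0,
                double time0, List par, int n_steps, int snap_every,
                int seed, bool do_move, bool do_poly) {
  Params p = read_params(par);
  Xoshiro rng((uint64_t)(uint32_t)seed * 0x9E3779B97f4A7C15ULL + 1234567ULL);

  int n0 = pos0.nrow();
  double pool = pool0;
  int max_beads = n0 + (p.spb > 0 ? (int)(pool / p.spb) : 0) + 1;

  std::vector<double> x(max_beads), y(max_beads), z(max_beads);
  std::vector<int> fil(max_beads), prv(max_beads, -1), nxtb(max_beads, -1);
  for (int i = 0; i < n0; i++) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    fil[i] = fil0[i];
    if (i > 0 && fil0[i] == fil0[i - 1]) { prv[i] = i - 1; nxtb[i - 1] = i; }
  }
  // filament bookkeeping: head and barbed tail per filament, in id order
  std::vector<int> fids, head_of, tail_of;
  for (int i = 0; i < n0; i++) {
    if (i == 0 || fil0[i] != fil0[i - 1]) {
      fids.push_back(fil0[i]);
      head_of.push_back(i);
      tail_of.push_back(i);
    } else {
      tail_of.back() = i;
    }
  }
  int nf = (int)fids.size();
  int n = n0;

  double noise = (p.kT > 0.0) ? std::sqrt(2.0 * p.kT * p.dt / p.gamma) : 0.0;
  double inv_gamma_dt = p.dt / p.gamma;
  double R_clamp = p.R + 0.04 * p.l0;  // hard cap: confinement invariant
  double p_add = p.poly_rate * p.dt;

  // Verlet list. Rebuild when any bead has moved further than a fraction of
  // the skin since the last rebuild; the exact displacement check runs every
  // few steps, bounded between checks by the running per-step maximum.
  double skin = std::max(0.8 * p.r_c, 0.1);
  double r_v = p.r_c + skin;
  std::vector<std::pair<int, int> > pairs;
  std::vector<double> rx(max_beads), ry(max_beads), rz(max_beads);
  CellGrid grid;
  bool need_pairs = (p.k_atr > 0.0 || p.k_rep > 0.0) && nf > 1;
  bool list_valid = false;
  double win_acc = 0.0;  // bound on movement since last exact check
  int steps_since_check = 0;

  // flat bond / triplet lists (rebuilt only when topology changes)
  std::vector<int> bonds, triplets;
  bool topo_valid = false;
  auto rebuild_topology = [&]() {
    bonds.clear(); triplets.clear();
    for (int fi = 0; fi < nf; fi++) {
      int a = head_of[fi];
      while (a >= 0) {
        int b = nxtb[a];
        if (b >= 0) {
          bonds.push_back(a); bonds.push_back(b);
          int c = nxtb[b];
          if (c >= 0) {
            triplets.push_back(a); triplets.push_back(b); triplets.push_back(c);
          }
        }
        a = b;
      }
    }
    topo_valid = true;
  };

  std::vector<double> fx(max_beads), fy(max_beads), fz(max_beads);

  List snaps;
  std::vector<double> snap_times;
  bool aborted = false;
  std::string abort_msg;

  auto rebuild = [&]() {
    pairs.clear();
    grid.build(x, y, z, n, r_v);
    double r_v2 = r_v * r_v;
    for (int i = 0; i < n; i++) {
      int cxi = std::min(grid.nx - 1, (int)((x[i] - grid.x0) / grid.cs));
      int cyi = std::min(grid.ny - 1, (int)((y[i] - grid.y0) / grid.cs));
      int czi = std::min(grid.nz - 1, (int)((z[i] - grid.z0) / grid.cs));
      for (int dz1 = -1; dz1 <= 1; dz1++)
        for (int dy1 = -1; dy1 <= 1; dy1++)
          for (int dx1 = -1; dx1 <= 1; dx1++) {
            int cx2 = cxi + dx1, cy2 = cyi + dy1, cz2 = czi + dz1;
            if (cx2 < 0 || cy2 < 0 || cz2 < 0 ||
                cx2 >= grid.nx || cy2 >= grid.ny || cz2 >= grid.nz)
              continue;
            int c = (cz2 * grid.ny + cy2) * grid.nx + cx2;
            for (int j = grid.head[c]; j >= 0; j = grid.nxt[j]) {
              if (j <= i || fil[j] == fil[i]) continue;
              double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
              if (ddx * ddx + ddy * ddy + ddz * ddz < r_v2)
                pairs.push_back(std::make_pair(i, j));
            }
          }
    }
    for (int i = 0; i < n; i++) { rx[i] = x[i]; ry[i] = y[i]; rz[i] = z[i]; }
    list_valid = true;
    win_acc = 0.0;
    steps_since_check = 0;
  };

  auto take_snapshot = [&](double t) {
    NumericMatrix P(n, 3);
    IntegerVector f(n);
    int k = 0;
    for (int fi = 0; fi < nf; fi++)
      for (int b = head_of[fi]; b >= 0; b = nxtb[b]) {
        P(k, 0) = x[b]; P(k, 1) = y[b]; P(k, 2) = z[b];
        f[k] = fids[fi];
        k++;
      }
    snaps.push_back(List::create(_["positions"] = P, _["filament"] = f,
                                 _["monomer_pool"] = pool, _["time"] = t));
    snap_times.push_back(t);
  };

  double t = time0;
  int check_every = 200;

  double* X = x.data(); double* Y = y.data(); double* Z = z.data();
  double* FX = fx.data(); double* FY = fy.data(); double* FZ = fz.data();
  double R_clamp2 = R_clamp * R_clamp;

  for (int step = 0; step < n_steps; step++) {
    if (do_move) {
      if (!topo_valid) rebuild_topology();
      if (need_pairs) {
        if (!list_valid) rebuild();
        else if (win_acc > 0.04 * skin || steps_since_check >= 16) {
          double m2 = 0.0;
          for (int i = 0; i < n; i++) {
            double ddx = x[i] - rx[i], ddy = y[i] - ry[i], ddz = z[i] - rz[i];
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 > m2) m2 = d2;
          }
          if (m2 > 0.45 * skin * 0.45 * skin) rebuild();
          else { win_acc = 0.0; steps_since_check = 0; }
        }
      }
      std::fill(fx.begin(), fx.begin() + n, 0.0);
      std::fill(fy.begin(), fy.begin() + n, 0.0);
      std::fill(fz.begin(), fz.begin() + n, 0.0);
      for (size_t q = 0; q < bonds.size(); q += 2)
        spring_pair(X, Y, Z, bonds[q], bonds[q + 1], p.k_spring, p.l0,
                    FX, FY, FZ);
      if (p.kappa_bend > 0)
        for (size_t q = 0; q < triplets.size(); q += 3)
          bend_triplet(X, Y, Z, triplets[q], triplets[q + 1], triplets[q + 2],
                       p.kappa_bend, FX, FY, FZ);
      if (need_pairs) {
        double rc2 = p.r_c * p.r_c;
        for (size_t q = 0; q < pairs.size(); q++) {
          int i = pairs[q].first, j = pairs[q].second;
          double ddx = X[j] - X[i], ddy = Y[j] - Y[i], ddz = Z[j] - Z[i];
          if (ddx * ddx + ddy * ddy + ddz * ddz < rc2)
            crosslink_pair(X, Y, Z, i, j, p, FX, FY, FZ);
        }
      }
      for (int i = 0; i < n; i++)
        boundary_bead(X, Y, Z, i, p, FX, FY, FZ);
      // Euler-Maruyama update + hard radial cap
      double step_max_d2 = 0.0;
      for (int i = 0; i < n; i++) {
        double dx1 = FX[i] * inv_gamma_dt;
        double dy1 = FY[i] * inv_gamma_dt;
        double dz1 = FZ[i] * inv_gamma_dt;
        if (noise > 0.0) {
          dx1 += noise * rng.norm();
          dy1 += noise * rng.norm();
          dz1 += noise * rng.norm();
        }
        X[i] += dx1; Y[i] += dy1; Z[i] += dz1;
        double d2 = dx1 * dx1 + dy1 * dy1 + dz1 * dz1;
        if (d2 > step_max_d2) step_max_d2 = d2;
        double r2 = X[i] * X[i] + Y[i] * Y[i] + Z[i] * Z[i];
        if (r2 > R_clamp2) {
          double s = R_clamp / std::sqrt(r2);
          X[i] *= s; Y[i] *= s; Z[i] *= s;
        }
      }
      win_acc += std::sqrt(step_max_d2);
      steps_since_check++;
    }
    if (do_poly && p.poly_rate > 0.0) {
      for (int fi = 0; fi < nf && pool >= p.spb; fi++) {
        if (rng.unif() >= p_add) continue;
        int tl = tail_of[fi];
        int pv = prv[tl];
        double tx1 = 0, ty1 = 0, tz1 = 1;
        if (pv >= 0) {
          tx1 = x[tl] - x[pv]; ty1 = y[tl] - y[pv]; tz1 = z[tl] - z[pv];
        }
        tx1 += p.poly_angle_sd * rng.norm();
        ty1 += p.poly_angle_sd * rng.norm();
        tz1 += p.poly_angle_sd * rng.norm();
        double nt = std::sqrt(tx1 * tx1 + ty1 * ty1 + tz1 * tz1);
        if (nt < 1e-12) { tx1 = 0; ty1 = 0; tz1 = 1; nt = 1; }
        double nxp = x[tl] + p.l0 * tx1 / nt;
        double nyp = y[tl] + p.l0 * ty1 / nt;
        double nzp = z[tl] + p.l0 * tz1 / nt;
        double rr = std::sqrt(nxp * nxp + nyp * nyp + nzp * nzp);
        double rin = p.R - 0.02 * p.l0;
        if (rr > rin) { nxp *= rin / rr; nyp *= rin / rr; nzp *= rin / rr; }
        x[n] = nxp; y[n] = nyp; z[n] = nzp;
        fil[n] = fids[fi];
        prv[n] = tl; nxtb[n] = -1; nxtb[tl] = n;
        tail_of[fi] = n;
        n++;
        pool -= p.spb;
        list_valid = false;   // new bead: pair list stale
        topo_valid = false;  // and bond/triplet lists too
      }
    }
    t += p.dt;
    if ((step + 1) % check_every == 0 || step + 1 == n_steps) {
      bool bad = false;
      for (int i = 0; i < n; i++)
        if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i])) {
          bad = true; break;
        }
      if (bad) {
        aborted = true;
        abort_msg = "non-finite coordinate at t=" + std::to_string(t);
        take_snapshot(t);
        break;
      }
    }
    if (snap_every > 0 && (step + 1) % snap_every == 0 && step + 1 != n_steps)
      take_snapshot(t);
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  if (!aborted) take_snapshot(t);

  // final state in chain order
  NumericMatrix P(n, 3);
  IntegerVector f(n);
  int k = 0;
  for (int fi = 0; fi < nf; fi++)
    for (int b = head_of[fi]; b >= 0; b = nxtb[b]) {
      P(k, 0) = x[b]; P(k, 1) = y[b]; P(k, 2) = z[b];
      f[k] = fids[fi];
      k++;
    }
  return List::create(_["positions"] = P, _["filament"] = f,
                      _["monomer_pool"] = pool, _["time"] = t,
                      _["snapshots"] = snaps,
                      _["snapshot_times"] = wrap(snap_times),
                      _["aborted"] = aborted, _["abort_message"] = abort_msg);
}

// ---------------------------------------------------------------------------
// Cross-filament proximity pairs (cell grid); bundle-graph construction.
// Returns a 2-column matrix of 1-based bead indices i < j with
// |x_i - x_j| < cutoff and fil[i] != fil[j].
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cross_pairs_cpp(NumericMatrix pos, IntegerVector fil,
                              double cutoff) {
  int n = pos.nrow();
  if (n == 0) return IntegerMatrix(0, 2);
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; i++) { x[i] = pos(i, 0); y[i] = pos(i, 1); z[i] = pos(i, 2); }
  CellGrid grid;
  grid.build(x, y, z, n, cutoff);
  double c2 = cutoff * cutoff;
  std::vector<int> ii, jj;
  for (int i = 0; i < n; i++) {
    int cxi = std::min(grid.nx - 1, (int)((x[i] - grid.x0) / grid.cs));
    int cyi = std::min(grid.ny - 1, (int)((y[i] - grid.y0) / grid.cs));
    int czi = std::min(grid.nz - 1, (int)((z[i] - grid.z0) / grid.cs));
    for (int dz1 = -1; dz1 <= 1; dz1++)
      for (int dy1 = -1; dy1 <= 1; dy1++)
        for (int dx1 = -1; dx1 <= 1; dx1++) {
          int cx2 = cxi + dx1, cy2 = cyi + dy1, cz2 = czi + dz1;
          if (cx2 < 0 || cy2 < 0 || cz2 < 0 ||
              cx2 >= grid.nx || cy2 >= grid.ny || cz2 >= grid.nz)
            continue;
          int c = (cz2 * grid.ny + cy2) * grid.nx + cx2;
          for (int j = grid.head[c]; j >= 0; j = grid.nxt[j]) {
            if (j <= i || fil[j] == fil[i]) continue;
            double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) {
              ii.push_back(i + 1);
              jj.push_back(j + 1);
            }
          }
        }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); k++) { out(k, 0) = ii[k]; out(k, 1) = jj[k]; }
  return out;
}
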