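// Simulation core: pair kernels, neighbor lists, Langevin / Velocity-Verlet
// propagation with orientation dynamics and rigid-body nanoparticles.
// All quantities in reduced units (length sigma = bead radius, mass m,
// time tau, energy eps).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <array>
#include <chrono>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++, ziggurat normals (Marsaglia-Tsang).
// Self-contained so trajectories are bit-reproducible for a given seed,
// independent of R's RNG state.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion
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
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // hand out both 32-bit halves of each 64-bit draw
  uint64_t cache = 0;
  bool have_cache = false;
  inline uint32_t next32() {
    if (have_cache) { have_cache = false; return (uint32_t)(cache >> 32); }
    cache = next();
    have_cache = true;
    return (uint32_t)cache;
  }
};

// Ziggurat tables for the standard normal (128 layers).
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static bool zig_ready = false;

static void zig_setup() {
  if (zig_ready) return;
  const double m1 = 2147483648.0;
  double dn = 3.442619855899, tn = dn;
  const double vn = 9.91256303526217e-3;
  double q = vn / std::exp(-0.5 * dn * dn);
  zig_kn[0] = (uint32_t)((dn / q) * m1);
  zig_kn[1] = 0;
  zig_wn[0] = q / m1;
  zig_wn[127] = dn / m1;
  zig_fn[0] = 1.0;
  zig_fn[127] = std::exp(-0.5 * dn * dn);
  for (int i = 126; i >= 1; i--) {
    dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
    zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
    tn = dn;
    zig_fn[i] = std::exp(-0.5 * dn * dn);
    zig_wn[i] = dn / m1;
  }
  zig_ready = true;
}

static inline double zig_normal(Xoshiro &rng) {
  const double r = 3.442619855899;
  for (;;) {
    int32_t hz = (int32_t)rng.next32();
    uint32_t iz = ((uint32_t)hz) & 127u;
    if ((uint32_t)std::abs(hz) < zig_kn[iz]) return hz * zig_wn[iz];
    if (iz == 0) {  // base strip: tail
      double x, y;
      do {
        x = -std::log(rng.unif()) / r;
        y = -std::log(rng.unif());
      } while (y + y < x * x);
      return (hz > 0) ? r + x : -(r + x);
    }
    double x = hz * zig_wn[iz];
    if (zig_fn[iz] + rng.unif() * (zig_fn[iz - 1] - zig_fn[iz]) <
        std::exp(-0.5 * x * x))
      return x;
  }
}

// [[Rcpp::export]]
NumericVector gp_rng_normal(int seed, int n) {
  zig_setup();
  Xoshiro rng((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = zig_normal(rng);
  return out;
}

// ---------------------------------------------------------------------------
// Small vector helpers
// ---------------------------------------------------------------------------

static inline double mimg(double d, double box) {
  return d - box * std::nearbyint(d / box);
}
static inline double mimg2(double d, double box, double invbox) {
  return d - box * std::nearbyint(d * invbox);
}
// minimum image for differences of wrapped coordinates (|d| < box)
static inline double mimgw(double d, double box, double half) {
  if (d > half) return d - box;
  if (d < -half) return d + box;
  return d;
}

struct V3 { double x, y, z; };
static inline V3 v3(double x, double y, double z) { V3 v{x, y, z}; return v; }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s*a.x, s*a.y, s*a.z); }
static inline double dot(V3 a, V3 b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(V3 a) { return std::sqrt(dot(a, a)); }

static inline double ipow_int(double c, int n) {
  double r = 1.0, b = c;
  while (n > 0) { if (n & 1) r *= b; b *= b; n >>= 1; }
  return r;
}

// ---------------------------------------------------------------------------
// Pair kernels
// ---------------------------------------------------------------------------

// 12-6 LJ, cut-and-shifted. Returns energy; *fr = -dU/dr (force magnitude on
// the separation coordinate; positive = repulsive).
static inline double lj_eval(double r2, double eps, double sigma, double rc2,
                             double eshift, double *fr_over_r) {
  if (r2 >= rc2) { *fr_over_r = 0.0; return 0.0; }
  double s2 = sigma * sigma / r2;
  double s6 = s2 * s2 * s2;
  double s12 = s6 * s6;
  double e = 4.0 * eps * (s12 - s6) - eshift;
  // -dU/dr / r = 24 eps (2 s12 - s6) / r^2
  *fr_over_r = 24.0 * eps * (2.0 * s12 - s6) / r2;
  return e;
}

struct NPParams {
  double eps, rmin, rcut, mu, theta0;
  int zeta;
  double s0, w;      // precomputed sin(theta0) and pi / (2 (rcut - rmin))
  // cubic-Hermite table of the attraction envelope
  // h(r) = cos^(2 zeta)(w (r - rmin)) on [rmin, rcut]; forces use the exact
  // derivative of the interpolant so energy and force stay consistent
  static const int TN = 1024;
  std::vector<double> ty, td;
  double tinv, tstep;
  void finish() {
    s0 = std::sin(theta0);
    w = M_PI / (2.0 * (rcut - rmin));
    tstep = (rcut - rmin) / TN;
    tinv = 1.0 / tstep;
    ty.resize(TN + 1); td.resize(TN + 1);
    for (int i = 0; i <= TN; ++i) {
      double psi = w * i * tstep;
      double c = std::cos(psi);
      double cp = ipow_int(c, 2 * zeta - 1);
      ty[i] = cp * c;
      td[i] = -2.0 * zeta * w * cp * std::sin(psi);
    }
  }
  // envelope and derivative at r (rmin <= r < rcut)
  inline void envelope(double r, double *h, double *dh) const {
    double u = (r - rmin) * tinv;
    int i = (int)u;
    if (i >= TN) i = TN - 1;
    double t = u - i;
    double y0 = ty[i], y1 = ty[i + 1];
    double d0 = td[i] * tstep, d1 = td[i + 1] * tstep;
    double t2 = t * t, t3 = t2 * t;
    *h = (2*t3 - 3*t2 + 1) * y0 + (t3 - 2*t2 + t) * d0 +
         (-2*t3 + 3*t2) * y1 + (t3 - t2) * d1;
    *dh = ((6*t2 - 6*t) * y0 + (3*t2 - 4*t + 1) * d0 +
           (-6*t2 + 6*t) * y1 + (3*t2 - 2*t) * d1) * tinv;
  }
};

// Orientation-weighted soft-core membrane potential between two shell beads.
// rvec = r_j - r_i. Outputs force on j (fj; fi = -fj) and the orientation
// generalized forces gi = -dU/dn_i, gj = -dU/dn_j.
static inline double np_eval(V3 rvec, V3 ni, V3 nj, const NPParams &p,
                             double eps, double mu,
                             V3 *fj, V3 *gi, V3 *gj) {
  double r2 = dot(rvec, rvec);
  if (r2 >= p.rcut * p.rcut || r2 <= 0.0) {
    *fj = v3(0,0,0); *gi = v3(0,0,0); *gj = v3(0,0,0);
    return 0.0;
  }
  double invr = 1.0 / std::sqrt(r2);
  double r = r2 * invr;
  V3 rh = invr * rvec;
  double s0 = p.s0;
  double nidotnj = dot(ni, nj);
  double nir = dot(ni, rh), njr = dot(nj, rh);
  double a = nidotnj - nir * njr + s0 * (dot(nj, rh) - dot(ni, rh)) - s0 * s0;
  double phi = 1.0 + mu * (a - 1.0);

  double u, dudr, duda;
  if (r < p.rmin) {
    double q2 = p.rmin * p.rmin / r2;
    double uR = eps * (q2 * q2 - 2.0 * q2);
    double duRdr = eps * (-4.0 * q2 * q2 + 4.0 * q2) * invr;
    u = uR + (1.0 - phi) * eps;
    dudr = duRdr;
    duda = -mu * eps;
  } else {
    double h, dh;
    p.envelope(r, &h, &dh);
    double uA = -eps * h;
    u = uA * phi;
    dudr = -eps * dh * phi;
    duda = mu * uA;
  }

  // da/drhat, projected through d rhat/d rvec = (I - rh rh^T)/r
  V3 dadrh = v3(-njr * ni.x - nir * nj.x + s0 * (nj.x - ni.x),
                -njr * ni.y - nir * nj.y + s0 * (nj.y - ni.y),
                -njr * ni.z - nir * nj.z + s0 * (nj.z - ni.z));
  double proj = dot(dadrh, rh);
  V3 dadr = invr * (dadrh - proj * rh);
  V3 dUdrvec = dudr * rh + duda * dadr;
  *fj = (-1.0) * dUdrvec;
  // da/dni = nj - njr*rh - s0*rh ; da/dnj = ni - nir*rh + s0*rh
  *gi = (-duda) * (nj - (njr + s0) * rh);
  *gj = (-duda) * (ni - (nir - s0) * rh);
  return u;
}

// [[Rcpp::export]]
List np_pair_cpp(NumericVector rvec, NumericVector ni, NumericVector nj,
                 double eps, double rmin, double rcut, int zeta, double mu,
                 double theta0) {
  NPParams p;
  p.eps = eps; p.rmin = rmin; p.rcut = rcut; p.mu = mu; p.theta0 = theta0;
  p.zeta = zeta;
  p.finish();
  V3 r = v3(rvec[0], rvec[1], rvec[2]);
  V3 a = v3(ni[0], ni[1], ni[2]), b = v3(nj[0], nj[1], nj[2]);
  V3 fj, gi, gj;
  double u = np_eval(r, a, b, p, eps, mu, &fj, &gi, &gj);
  return List::create(
    _["energy"] = u,
    _["force_i"] = NumericVector::create(-fj.x, -fj.y, -fj.z),
    _["force_j"] = NumericVector::create(fj.x, fj.y, fj.z),
    _["gn_i"] = NumericVector::create(gi.x, gi.y, gi.z),
    _["gn_j"] = NumericVector::create(gj.x, gj.y, gj.z));
}

// [[Rcpp::export]]
List lj_pair_cpp(double r, double eps, double sigma, double cutoff) {
  double rc2 = cutoff * cutoff;
  double s6c = ipow_int(sigma / cutoff, 6);
  double eshift = 4.0 * eps * (s6c * s6c - s6c);
  double fr_r = 0.0;
  double e = lj_eval(r * r, eps, sigma, rc2, eshift, &fr_r);
  return List::create(_["energy"] = e, _["force"] = fr_r * r);
}

// ---------------------------------------------------------------------------
// System container used by the force loop and the integrator
// ---------------------------------------------------------------------------

struct Sim {
  int N;
  double box, invbox;
  std::vector<double> x, y, z;          // wrapped
  std::vector<double> ux, uy, uz;       // unwrapped
  std::vector<double> vx, vy, vz;
  std::vector<double> nx, ny, nz;       // orientation (np beads)
  std::vector<double> mass;
  std::vector<int> type;                // 1 polymer, 2 node, 3 np
  std::vector<int> npid;                // 0 = none, else 1..n_np
  int n_np;
  std::vector<int> rigid;               // per NP flag

  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_k, b_r0;
  std::vector<std::array<int, 8>> excl;   // bonded (1-2) neighbors per bead
  std::vector<int> n_excl;
  inline bool excluded(int i, int j) const {
    for (int k = 0; k < n_excl[i]; ++k) if (excl[i][k] == j) return true;
    return false;
  }

  // tethers
  std::vector<int> t_idx;
  std::vector<double> t_ax, t_ay, t_az;
  double tether_k;

  std::vector<double> np_se, np_muv;   // per-bead sqrt(eps_np) and mu
  // LJ tables (3x3)
  double lj_eps[3][3], lj_sig[3][3], lj_rc2[3][3], lj_shift[3][3];
  double lj_rl2[3][3];               // (cutoff + skin)^2 list radii
  NPParams np;
  double max_cut;

  // forces / orientation generalized forces
  std::vector<double> fx, fy, fz, gx, gy, gz;
  double e_bond, e_lj, e_np, e_tether;

  // neighbor lists: shell-involved pairs (rebuilt when anything moves
  // skin/2) and polymer-polymer pairs (big skin; tethered fibers move
  // little, so this list rebuilds rarely)
  double skin, skin_pp;
  std::vector<int> lj_pi, lj_pj;       // shell-polymer (and node) pairs
  std::vector<int> pp_pi, pp_pj;       // polymer-polymer pairs
  std::vector<int> np_pi, np_pj;       // shell-shell pairs
  std::vector<double> ref_x, ref_y, ref_z;
  std::vector<double> refp_x, refp_y, refp_z;
  std::vector<int> shell_idx, poly_idx;

};

static void sim_from_r(Sim &S, const List &sys, const List &par) {
  NumericMatrix pos = sys["positions"], vel = sys["velocities"],
                nor = sys["normals"], unw = sys["unwrapped"];
  IntegerVector tp = sys["bead_type_code"], np_id = sys["np_id_code"];
  NumericVector mass = sys["masses"];
  S.N = pos.nrow();
  S.box = as<double>(sys["box_length"]);
  S.invbox = 1.0 / S.box;
  S.x.resize(S.N); S.y.resize(S.N); S.z.resize(S.N);
  S.ux.resize(S.N); S.uy.resize(S.N); S.uz.resize(S.N);
  S.vx.resize(S.N); S.vy.resize(S.N); S.vz.resize(S.N);
  S.nx.assign(S.N, 0.0); S.ny.assign(S.N, 0.0); S.nz.assign(S.N, 0.0);
  S.mass.resize(S.N); S.type.resize(S.N); S.npid.resize(S.N);
  for (int i = 0; i < S.N; ++i) {
    S.x[i] = pos(i,0); S.y[i] = pos(i,1); S.z[i] = pos(i,2);
    S.ux[i] = unw(i,0); S.uy[i] = unw(i,1); S.uz[i] = unw(i,2);
    S.vx[i] = vel(i,0); S.vy[i] = vel(i,1); S.vz[i] = vel(i,2);
    if (!NumericMatrix::is_na(nor(i,0))) {
      S.nx[i] = nor(i,0); S.ny[i] = nor(i,1); S.nz[i] = nor(i,2);
    }
    S.mass[i] = mass[i];
    S.type[i] = tp[i];
    S.npid[i] = np_id[i];
  }
  S.n_np = as<int>(sys["n_np"]);
  IntegerVector rg = sys["rigid_code"];
  S.rigid.assign(rg.begin(), rg.end());

  NumericMatrix bonds = sys["bonds"];
  int nb = bonds.nrow();
  S.b_i.resize(nb); S.b_j.resize(nb); S.b_k.resize(nb); S.b_r0.resize(nb);
  S.excl.assign(S.N, std::array<int, 8>());
  S.n_excl.assign(S.N, 0);
  for (int b = 0; b < nb; ++b) {
    S.b_i[b] = (int)bonds(b,0) - 1;
    S.b_j[b] = (int)bonds(b,1) - 1;
    S.b_k[b] = bonds(b,2);
    S.b_r0[b] = bonds(b,3);
    int bi = S.b_i[b], bj = S.b_j[b];
    if (S.n_excl[bi] >= 8 || S.n_excl[bj] >= 8)
      stop("a bead has more than 8 bonds");
    S.excl[bi][S.n_excl[bi]++] = bj;
    S.excl[bj][S.n_excl[bj]++] = bi;
  }

  IntegerVector ti = sys["tether_index"];
  NumericMatrix ta = sys["tether_anchor"];
  S.t_idx.resize(ti.size());
  S.t_ax.resize(ti.size()); S.t_ay.resize(ti.size()); S.t_az.resize(ti.size());
  for (int k = 0; k < ti.size(); ++k) {
    S.t_idx[k] = ti[k] - 1;
    S.t_ax[k] = ta(k,0); S.t_ay[k] = ta(k,1); S.t_az[k] = ta(k,2);
  }
  S.tether_k = as<double>(par["tether_k"]);

  NumericMatrix le = par["lj_eps"], ls = par["lj_sigma"], lr = par["lj_cutoff"];
  S.max_cut = 0.0;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) {
    S.lj_eps[a][b] = le(a,b);
    S.lj_sig[a][b] = ls(a,b);
    double rc = lr(a,b);
    S.lj_rc2[a][b] = rc * rc;
    double s6 = ipow_int(ls(a,b) / rc, 6);
    S.lj_shift[a][b] = 4.0 * le(a,b) * (s6 * s6 - s6);
    if (le(a,b) > 0.0 && rc > S.max_cut) S.max_cut = rc;
  }
  S.np.eps = as<double>(par["np_eps"]);
  S.np.rmin = as<double>(par["np_rmin"]);
  S.np.rcut = as<double>(par["np_rcut"]);
  S.np.zeta = as<int>(par["np_zeta"]);
  S.np.mu = as<double>(par["np_mu"]);
  S.np.theta0 = as<double>(par["np_theta0"]);
  S.np.finish();
  S.np_se.assign(S.N, std::sqrt(S.np.eps));
  S.np_muv.assign(S.N, S.np.mu);
  if (par.containsElementNamed("np_eps_bead")) {
    NumericVector ev = par["np_eps_bead"], mv = par["np_mu_bead"];
    for (int i = 0; i < S.N; ++i) {
      S.np_se[i] = std::sqrt(ev[i]);
      S.np_muv[i] = mv[i];
    }
  }
  if (S.np.rcut > S.max_cut) S.max_cut = S.np.rcut;
  S.skin = par.containsElementNamed("skin") ? as<double>(par["skin"]) : 0.4;
  S.skin_pp = 2.0;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) {
    double sk = (a < 2 && b < 2) ? S.skin_pp : S.skin;
    double rl = std::sqrt(S.lj_rc2[a][b]) + sk;
    S.lj_rl2[a][b] = rl * rl;
  }
  S.shell_idx.clear(); S.poly_idx.clear();
  for (int i = 0; i < S.N; ++i)
    (S.type[i] == 3 ? S.shell_idx : S.poly_idx).push_back(i);

  S.fx.assign(S.N, 0.0); S.fy.assign(S.N, 0.0); S.fz.assign(S.N, 0.0);
  S.gx.assign(S.N, 0.0); S.gy.assign(S.N, 0.0); S.gz.assign(S.N, 0.0);
}

// Build Verlet lists via cell binning (all-pairs fallback for small boxes).
// Two passes: a shell-bead-centered scan over a coarse grid (shell-shell and
// shell-polymer pairs, which carry the long cutoffs) and a polymer-only scan
// over a fine grid for the short-ranged polymer-polymer pairs.
__attribute__((target_clones("default", "arch=x86-64-v3")))
static void build_lists(Sim &S, bool do_np = true, bool do_pp = true) {
  if (do_np) {
    S.lj_pi.clear(); S.lj_pj.clear();
    S.np_pi.clear(); S.np_pj.clear();
  }
  double rl_np = S.np.rcut + S.skin;
  double rl_np2 = rl_np * rl_np;

  auto consider = [&](int i, int j, double r2) {
    if (S.type[i] == 3 && S.type[j] == 3 && S.npid[i] == S.npid[j]) {
      if (S.rigid[S.npid[i] - 1]) return;
      if (r2 < rl_np2) { S.np_pi.push_back(i); S.np_pj.push_back(j); }
    } else if (S.type[i] == 3 || S.type[j] == 3) {
      int a = S.type[i] - 1, b = S.type[j] - 1;
      if (S.lj_eps[a][b] <= 0.0) return;
      if (r2 < S.lj_rl2[a][b]) {
        S.lj_pi.push_back(i); S.lj_pj.push_back(j);
      }
    } else {
      int a = S.type[i] - 1, b = S.type[j] - 1;
      if (S.lj_eps[a][b] <= 0.0) return;
      if (r2 < S.lj_rl2[a][b] && !S.excluded(i, j)) {
        S.pp_pi.push_back(i); S.pp_pj.push_back(j);
      }
    }
  };

  double cut_np = std::max({S.np.rcut, std::sqrt(S.lj_rc2[2][0]),
                            std::sqrt(S.lj_rc2[2][1])}) + S.skin;
  double cut_pp = std::max(std::sqrt(S.lj_rl2[0][0]),
                           std::sqrt(S.lj_rl2[0][1]));
  int nc_np = (int)std::floor(S.box / cut_np);
  int nc_pp = (int)std::floor(S.box / cut_pp);
  if (nc_np < 3 || nc_pp < 3) {
    S.pp_pi.clear(); S.pp_pj.clear();
    for (int i = 0; i < S.N; ++i)
      for (int j = i + 1; j < S.N; ++j) {
        double dx = mimg2(S.x[i] - S.x[j], S.box, S.invbox);
        double dy = mimg2(S.y[i] - S.y[j], S.box, S.invbox);
        double dz = mimg2(S.z[i] - S.z[j], S.box, S.invbox);
        consider(i, j, dx*dx + dy*dy + dz*dz);
      }
    S.ref_x = S.x; S.ref_y = S.y; S.ref_z = S.z;
    S.refp_x = S.x; S.refp_y = S.y; S.refp_z = S.z;
    return;
  }

  auto bin = [&](const std::vector<int> &which, int nc,
                 std::vector<int> &head, std::vector<int> &nxt) {
    head.assign(nc * nc * nc, -1);
    double inv_cs = nc * S.invbox;
    for (int i : which) {
      int cx = (int)(S.x[i] * inv_cs); if (cx >= nc) cx = nc - 1;
      int cy = (int)(S.y[i] * inv_cs); if (cy >= nc) cy = nc - 1;
      int cz = (int)(S.z[i] * inv_cs); if (cz >= nc) cz = nc - 1;
      int c = (cz * nc + cy) * nc + cx;
      nxt[i] = head[c]; head[c] = i;
    }
  };

  const std::vector<int> &shell = S.shell_idx, &poly = S.poly_idx;
  std::vector<int> head, nxt(S.N, -1);
  // pass 1: all beads counting-sorted into cell order, scan around shells
  if (do_np) {
    int ncell = nc_np * nc_np * nc_np;
    double inv_cs = nc_np * S.invbox;
    std::vector<int> cell_of(S.N), start(ncell + 1, 0);
    for (int i = 0; i < S.N; ++i) {
      int cx = (int)(S.x[i] * inv_cs); if (cx >= nc_np) cx = nc_np - 1;
      int cy = (int)(S.y[i] * inv_cs); if (cy >= nc_np) cy = nc_np - 1;
      int cz = (int)(S.z[i] * inv_cs); if (cz >= nc_np) cz = nc_np - 1;
      int c = (cz * nc_np + cy) * nc_np + cx;
      cell_of[i] = c;
      ++start[c + 1];
    }
    for (int c = 0; c < ncell; ++c) start[c + 1] += start[c];
    std::vector<int> fill = start;
    std::vector<double> sx(S.N), sy(S.N), sz(S.N);
    std::vector<int> sid(S.N);
    for (int i = 0; i < S.N; ++i) {
      int k = fill[cell_of[i]]++;
      sx[k] = S.x[i]; sy[k] = S.y[i]; sz[k] = S.z[i]; sid[k] = i;
    }
    for (int i : shell) {
      int c = cell_of[i];
      int cx = c % nc_np, cy = (c / nc_np) % nc_np, cz = c / (nc_np * nc_np);
      double xi = S.x[i], yi = S.y[i], zi = S.z[i];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ox = cx + dx; if (ox < 0) ox += nc_np; else if (ox >= nc_np) ox -= nc_np;
            int oy = cy + dy; if (oy < 0) oy += nc_np; else if (oy >= nc_np) oy -= nc_np;
            int oz = cz + dz; if (oz < 0) oz += nc_np; else if (oz >= nc_np) oz -= nc_np;
            int o = (oz * nc_np + oy) * nc_np + ox;
            for (int k = start[o]; k < start[o + 1]; ++k) {
              int j = sid[k];
              // shell-shell pairs once (i < j); shell-polymer always from i
              if (S.type[j] == 3 && j <= i) continue;
              double ddx = mimgw(xi - sx[k], S.box, 0.5 * S.box);
              double ddy = mimgw(yi - sy[k], S.box, 0.5 * S.box);
              double ddz = mimgw(zi - sz[k], S.box, 0.5 * S.box);
              consider(std::min(i, j), std::max(i, j),
                       ddx*ddx + ddy*ddy + ddz*ddz);
            }
          }
    }
    S.ref_x = S.x; S.ref_y = S.y; S.ref_z = S.z;
  }

  // pass 2: polymer-polymer on the fine grid
  if (do_pp) {
  S.pp_pi.clear(); S.pp_pj.clear();
  bin(poly, nc_pp, head, nxt);
  {
    double inv_cs = nc_pp * S.invbox;
    for (int i : poly) {
      int cx = (int)(S.x[i] * inv_cs); if (cx >= nc_pp) cx = nc_pp - 1;
      int cy = (int)(S.y[i] * inv_cs); if (cy >= nc_pp) cy = nc_pp - 1;
      int cz = (int)(S.z[i] * inv_cs); if (cz >= nc_pp) cz = nc_pp - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ox = cx + dx; if (ox < 0) ox += nc_pp; else if (ox >= nc_pp) ox -= nc_pp;
            int oy = cy + dy; if (oy < 0) oy += nc_pp; else if (oy >= nc_pp) oy -= nc_pp;
            int oz = cz + dz; if (oz < 0) oz += nc_pp; else if (oz >= nc_pp) oz -= nc_pp;
            int o = (oz * nc_pp + oy) * nc_pp + ox;
            for (int j = head[o]; j >= 0; j = nxt[j]) {
              if (j <= i) continue;
              double ddx = mimgw(S.x[i] - S.x[j], S.box, 0.5 * S.box);
              double ddy = mimgw(S.y[i] - S.y[j], S.box, 0.5 * S.box);
              double ddz = mimgw(S.z[i] - S.z[j], S.box, 0.5 * S.box);
              consider(i, j, ddx*ddx + ddy*ddy + ddz*ddz);
            }
          }
    }
  }
  S.refp_x = S.x; S.refp_y = S.y; S.refp_z = S.z;
  }
}

// rebuild when any bead has moved half the skin since the last build
__attribute__((target_clones("default", "arch=x86-64-v3")))
static bool need_rebuild(const Sim &S) {
  double lim = 0.25 * S.skin * S.skin;
  double mx = 0.0;
  const double *x = S.x.data(), *y = S.y.data(), *z = S.z.data();
  const double *rx = S.ref_x.data(), *ry = S.ref_y.data(),
               *rz = S.ref_z.data();
  for (int i = 0; i < S.N; ++i) {
    double dx = std::fabs(x[i] - rx[i]);
    double dy = std::fabs(y[i] - ry[i]);
    double dz = std::fabs(z[i] - rz[i]);
    dx = std::min(dx, S.box - dx);
    dy = std::min(dy, S.box - dy);
    dz = std::min(dz, S.box - dz);
    mx = std::max(mx, dx*dx + dy*dy + dz*dz);
  }
  return mx > lim;
}

static bool need_rebuild_pp(const Sim &S) {
  double lim = 0.25 * S.skin_pp * S.skin_pp;
  double mx = 0.0;
  for (int i : S.poly_idx) {
    double dx = std::fabs(S.x[i] - S.refp_x[i]);
    double dy = std::fabs(S.y[i] - S.refp_y[i]);
    double dz = std::fabs(S.z[i] - S.refp_z[i]);
    dx = std::min(dx, S.box - dx);
    dy = std::min(dy, S.box - dy);
    dz = std::min(dz, S.box - dz);
    mx = std::max(mx, dx*dx + dy*dy + dz*dz);
  }
  return mx > lim;
}

__attribute__((target_clones("default", "arch=x86-64-v3")))
static void compute_forces(Sim &S, bool need_gn = true) {
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  std::fill(S.gx.begin(), S.gx.end(), 0.0);
  std::fill(S.gy.begin(), S.gy.end(), 0.0);
  std::fill(S.gz.begin(), S.gz.end(), 0.0);
  S.e_bond = S.e_lj = S.e_np = S.e_tether = 0.0;

  double halfbox = 0.5 * S.box;
  // bonds: U = k (r - r0)^2
  for (size_t b = 0; b < S.b_i.size(); ++b) {
    int i = S.b_i[b], j = S.b_j[b];
    double dx = mimgw(S.x[j] - S.x[i], S.box, halfbox);
    double dy = mimgw(S.y[j] - S.y[i], S.box, halfbox);
    double dz = mimgw(S.z[j] - S.z[i], S.box, halfbox);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - S.b_r0[b];
    S.e_bond += S.b_k[b] * dr * dr;
    double fmag = -2.0 * S.b_k[b] * dr / r;  // on j along rvec
    S.fx[j] += fmag * dx; S.fy[j] += fmag * dy; S.fz[j] += fmag * dz;
    S.fx[i] -= fmag * dx; S.fy[i] -= fmag * dy; S.fz[i] -= fmag * dz;
  }

  // tethers: U = k d^2 (restores node to anchor)
  for (size_t t = 0; t < S.t_idx.size(); ++t) {
    int i = S.t_idx[t];
    double dx = mimg2(S.x[i] - S.t_ax[t], S.box, S.invbox);
    double dy = mimg2(S.y[i] - S.t_ay[t], S.box, S.invbox);
    double dz = mimg2(S.z[i] - S.t_az[t], S.box, S.invbox);
    S.e_tether += S.tether_k * (dx*dx + dy*dy + dz*dz);
    S.fx[i] -= 2.0 * S.tether_k * dx;
    S.fy[i] -= 2.0 * S.tether_k * dy;
    S.fz[i] -= 2.0 * S.tether_k * dz;
  }

  // LJ pairs (shell-polymer, then polymer-polymer)
  for (int pass = 0; pass < 2; ++pass) {
  const std::vector<int> &PI = pass ? S.pp_pi : S.lj_pi;
  const std::vector<int> &PJ = pass ? S.pp_pj : S.lj_pj;
  for (size_t p = 0; p < PI.size(); ++p) {
    int i = PI[p], j = PJ[p];
    double dx = mimgw(S.x[j] - S.x[i], S.box, halfbox);
    double dy = mimgw(S.y[j] - S.y[i], S.box, halfbox);
    double dz = mimgw(S.z[j] - S.z[i], S.box, halfbox);
    double r2 = dx*dx + dy*dy + dz*dz;
    int a = S.type[i] - 1, b = S.type[j] - 1;
    if (r2 >= S.lj_rc2[a][b]) continue;
    double fr_r;
    S.e_lj += lj_eval(r2, S.lj_eps[a][b], S.lj_sig[a][b], S.lj_rc2[a][b],
                      S.lj_shift[a][b], &fr_r);
    // force on j = +fr_r * rvec (repulsive pushes j away from i)
    S.fx[j] += fr_r * dx; S.fy[j] += fr_r * dy; S.fz[j] += fr_r * dz;
    S.fx[i] -= fr_r * dx; S.fy[i] -= fr_r * dy; S.fz[i] -= fr_r * dz;
  }
  }

  // orientation-weighted shell pairs
  double rc2 = S.np.rcut * S.np.rcut;
  for (size_t p = 0; p < S.np_pi.size(); ++p) {
    int i = S.np_pi[p], j = S.np_pj[p];
    double dx = mimgw(S.x[j] - S.x[i], S.box, halfbox);
    double dy = mimgw(S.y[j] - S.y[i], S.box, halfbox);
    double dz = mimgw(S.z[j] - S.z[i], S.box, halfbox);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= rc2) continue;
    V3 rv = v3(dx, dy, dz);
    V3 ni = v3(S.nx[i], S.ny[i], S.nz[i]);
    V3 nj = v3(S.nx[j], S.ny[j], S.nz[j]);
    V3 fj, gi, gj;
    double peps = S.np_se[i] * S.np_se[j];
    double pmu = 0.5 * (S.np_muv[i] + S.np_muv[j]);
    S.e_np += np_eval(rv, ni, nj, S.np, peps, pmu, &fj, &gi, &gj);
    S.fx[j] += fj.x; S.fy[j] += fj.y; S.fz[j] += fj.z;
    S.fx[i] -= fj.x; S.fy[i] -= fj.y; S.fz[i] -= fj.z;
    if (need_gn) {
      S.gx[i] += gi.x; S.gy[i] += gi.y; S.gz[i] += gi.z;
      S.gx[j] += gj.x; S.gy[j] += gj.y; S.gz[j] += gj.z;
    }
  }
}

// [[Rcpp::export]]
List compute_forces_cpp(List sys, List par) {
  zig_setup();
  Sim S;
  sim_from_r(S, sys, par);
  build_lists(S);
  compute_forces(S);
  NumericMatrix f(S.N, 3), g(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    f(i,0) = S.fx[i]; f(i,1) = S.fy[i]; f(i,2) = S.fz[i];
    g(i,0) = S.gx[i]; g(i,1) = S.gy[i]; g(i,2) = S.gz[i];
  }
  double pe = S.e_bond + S.e_lj + S.e_np + S.e_tether;
  return List::create(
    _["forces"] = f, _["normal_torques"] = g, _["potential_energy"] = pe,
    _["breakdown"] = NumericVector::create(
      _["bond"] = S.e_bond, _["pair_lj"] = S.e_lj, _["pair_np"] = S.e_np,
      _["tether"] = S.e_tether));
}

// ---------------------------------------------------------------------------
// Rigid bodies
// ---------------------------------------------------------------------------

struct Quat { double w, x, y, z; };

static inline void quat_to_mat(const Quat &q, double R[3][3]) {
  double w=q.w, x=q.x, y=q.y, z=q.z;
  R[0][0] = 1-2*(y*y+z*z); R[0][1] = 2*(x*y-w*z);   R[0][2] = 2*(x*z+w*y);
  R[1][0] = 2*(x*y+w*z);   R[1][1] = 1-2*(x*x+z*z); R[1][2] = 2*(y*z-w*x);
  R[2][0] = 2*(x*z-w*y);   R[2][1] = 2*(y*z+w*x);   R[2][2] = 1-2*(x*x+y*y);
}

static inline void mat3_inv(const double A[3][3], double Ai[3][3]) {
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  double id = 1.0 / det;
  Ai[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1]) * id;
  Ai[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1]) * id;
  Ai[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1]) * id;
  Ai[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0]) * id;
  Ai[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0]) * id;
  Ai[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0]) * id;
  Ai[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0]) * id;
  Ai[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0]) * id;
  Ai[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0]) * id;
}

static inline V3 mat_vec(const double R[3][3], V3 v) {
  return v3(R[0][0]*v.x + R[0][1]*v.y + R[0][2]*v.z,
            R[1][0]*v.x + R[1][1]*v.y + R[1][2]*v.z,
            R[2][0]*v.x + R[2][1]*v.y + R[2][2]*v.z);
}
static inline V3 mat_tvec(const double R[3][3], V3 v) {
  return v3(R[0][0]*v.x + R[1][0]*v.y + R[2][0]*v.z,
            R[0][1]*v.x + R[1][1]*v.y + R[2][1]*v.z,
            R[0][2]*v.x + R[1][2]*v.y + R[2][2]*v.z);
}

struct RigidBody {
  std::vector<int> beads;
  std::vector<V3> b, nb;    // body-frame coordinates and normals
  double Ib[3][3];          // body-frame inertia
  double M;
  V3 com, vcom, L;          // com unwrapped, velocity, angular momentum (space)
  Quat q;
};

// ---------------------------------------------------------------------------
// run_simulation
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
__attribute__((target_clones("default", "arch=x86-64-v3")))
List run_simulation_cpp(List sys, List par, List cfg) {
  zig_setup();
  Sim S;
  sim_from_r(S, sys, par);

  double dt = as<double>(cfg["dt"]);
  long nsteps = (long)as<double>(cfg["nsteps"]);
  double gamma = as<double>(cfg["gamma"]);
  double gamma_r = as<double>(cfg["gamma_r"]);
  double kT = as<double>(cfg["temperature"]);
  int out_every = as<int>(cfg["output_interval"]);
  int thermo_every = cfg.containsElementNamed("thermostat_interval") ?
    as<int>(cfg["thermostat_interval"]) : 1;
  bool profile = cfg.containsElementNamed("profile") && as<bool>(cfg["profile"]);
  double t_kick = 0, t_rigid = 0, t_rebuild = 0, t_forces = 0, t_thermo = 0,
         t_norm = 0, t_rec = 0;
  int n_rebuilds = 0;
  auto tick = [&]() { return std::chrono::steady_clock::now(); };
  auto tock = [&](std::chrono::steady_clock::time_point t0, double &acc) {
    acc += std::chrono::duration<double>(tick() - t0).count();
  };
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  Xoshiro rng(seed);

  // rigid-body setup
  std::vector<RigidBody> rb;
  std::vector<int> bead_rigid(S.N, -1);
  for (int k = 0; k < S.n_np; ++k) {
    if (!S.rigid[k]) continue;
    RigidBody B;
    for (int i = 0; i < S.N; ++i)
      if (S.npid[i] == k + 1) B.beads.push_back(i);
    int nb = (int)B.beads.size();
    B.M = 0.0;
    B.com = v3(0,0,0);
    for (int i : B.beads) {
      B.com = B.com + S.mass[i] * v3(S.ux[i], S.uy[i], S.uz[i]);
      B.M += S.mass[i];
    }
    B.com = (1.0 / B.M) * B.com;
    B.vcom = v3(0,0,0);
    for (int i : B.beads) B.vcom = B.vcom + (S.mass[i]/B.M) * v3(S.vx[i], S.vy[i], S.vz[i]);
    for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c) B.Ib[a][c] = 0.0;
    B.L = v3(0,0,0);
    B.b.resize(nb); B.nb.resize(nb);
    for (int t = 0; t < nb; ++t) {
      int i = B.beads[t];
      V3 d = v3(S.ux[i], S.uy[i], S.uz[i]) - B.com;
      B.b[t] = d;
      B.nb[t] = v3(S.nx[i], S.ny[i], S.nz[i]);
      double m = S.mass[i];
      double dd = dot(d, d);
      B.Ib[0][0] += m * (dd - d.x*d.x); B.Ib[0][1] -= m * d.x*d.y; B.Ib[0][2] -= m * d.x*d.z;
      B.Ib[1][0] -= m * d.y*d.x; B.Ib[1][1] += m * (dd - d.y*d.y); B.Ib[1][2] -= m * d.y*d.z;
      B.Ib[2][0] -= m * d.z*d.x; B.Ib[2][1] -= m * d.z*d.y; B.Ib[2][2] += m * (dd - d.z*d.z);
      V3 vrel = v3(S.vx[i], S.vy[i], S.vz[i]) - B.vcom;
      B.L = B.L + S.mass[i] * cross(d, vrel);
      bead_rigid[i] = (int)rb.size();
    }
    B.q = Quat{1, 0, 0, 0};
    rb.push_back(B);
  }

  // trajectory storage
  long nframes = nsteps / out_every + 1;
  NumericVector times(nframes);
  NumericVector wr(nframes * S.N * 3), uw(nframes * S.N * 3);
  std::vector<int> npb;  // shell bead indices
  for (int i = 0; i < S.N; ++i) if (S.type[i] == 3) npb.push_back(i);
  int Nnp = (int)npb.size();
  NumericVector nrm(nframes * Nnp * 3);
  NumericVector cen((size_t)nframes * std::max(S.n_np,1) * 3);
  NumericVector pe_v(nframes), ke_v(nframes), tk_v(nframes);

  build_lists(S);
  compute_forces(S);

  auto record = [&](long f, double t) {
    times[f] = t;
    for (int i = 0; i < S.N; ++i) {
      wr[f + nframes * (i + (long)S.N * 0)] = S.x[i];
      wr[f + nframes * (i + (long)S.N * 1)] = S.y[i];
      wr[f + nframes * (i + (long)S.N * 2)] = S.z[i];
      uw[f + nframes * (i + (long)S.N * 0)] = S.ux[i];
      uw[f + nframes * (i + (long)S.N * 1)] = S.uy[i];
      uw[f + nframes * (i + (long)S.N * 2)] = S.uz[i];
    }
    for (int t2 = 0; t2 < Nnp; ++t2) {
      int i = npb[t2];
      nrm[f + nframes * (t2 + (long)Nnp * 0)] = S.nx[i];
      nrm[f + nframes * (t2 + (long)Nnp * 1)] = S.ny[i];
      nrm[f + nframes * (t2 + (long)Nnp * 2)] = S.nz[i];
    }
    // per-NP centroids from unwrapped coordinates
    for (int k = 0; k < S.n_np; ++k) {
      double cx = 0, cy = 0, cz = 0; int cnt = 0;
      for (int i = 0; i < S.N; ++i) if (S.npid[i] == k + 1) {
        cx += S.ux[i]; cy += S.uy[i]; cz += S.uz[i]; ++cnt;
      }
      if (cnt > 0) { cx /= cnt; cy /= cnt; cz /= cnt; }
      cen[f + nframes * (k + (long)S.n_np * 0)] = cx;
      cen[f + nframes * (k + (long)S.n_np * 1)] = cy;
      cen[f + nframes * (k + (long)S.n_np * 2)] = cz;
    }
    double ke = 0.0;
    for (int i = 0; i < S.N; ++i)
      if (bead_rigid[i] < 0)
        ke += 0.5 * S.mass[i] * (S.vx[i]*S.vx[i] + S.vy[i]*S.vy[i] + S.vz[i]*S.vz[i]);
    int nfree = 0;
    for (int i = 0; i < S.N; ++i) if (bead_rigid[i] < 0) ++nfree;
    long dof = 3L * nfree;
    for (auto &B : rb) {
      ke += 0.5 * B.M * dot(B.vcom, B.vcom);
      double R[3][3]; quat_to_mat(B.q, R);
      double Is[3][3], tmp[3][3];
      for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c) {
        tmp[a][c] = R[a][0]*B.Ib[0][c] + R[a][1]*B.Ib[1][c] + R[a][2]*B.Ib[2][c];
      }
      for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c) {
        Is[a][c] = tmp[a][0]*R[c][0] + tmp[a][1]*R[c][1] + tmp[a][2]*R[c][2];
      }
      double Ii[3][3]; mat3_inv(Is, Ii);
      V3 om = mat_vec(Ii, B.L);
      ke += 0.5 * dot(om, B.L);
      dof += 6;
    }
    pe_v[f] = S.e_bond + S.e_lj + S.e_np + S.e_tether;
    ke_v[f] = ke;
    tk_v[f] = (dof > 0) ? 2.0 * ke / dof : 0.0;
    if (!std::isfinite(pe_v[f]) || !std::isfinite(ke))
      stop("simulation produced a non-finite energy at t = %f", t);
  };
  record(0, 0.0);

  double max_disp = 0.5;           // per-step blow-up guard (sigma)
  double dt_t = thermo_every * dt;  // thermostat kick interval
  double sq_noise = std::sqrt(2.0 * gamma * kT * dt_t);
  double sq_noise_r = std::sqrt(2.0 * kT * dt_t / gamma_r);

  // cached per-rigid net force / torque
  std::vector<V3> rF(rb.size()), rT(rb.size());
  auto rigid_net = [&]() {
    for (size_t k = 0; k < rb.size(); ++k) {
      RigidBody &B = rb[k];
      double R[3][3]; quat_to_mat(B.q, R);
      V3 F = v3(0,0,0), T = v3(0,0,0);
      for (size_t t = 0; t < B.beads.size(); ++t) {
        int i = B.beads[t];
        V3 f = v3(S.fx[i], S.fy[i], S.fz[i]);
        V3 arm = mat_vec(R, B.b[t]);
        F = F + f;
        T = T + cross(arm, f);
        V3 n = v3(S.nx[i], S.ny[i], S.nz[i]);
        V3 g = v3(S.gx[i], S.gy[i], S.gz[i]);
        T = T + cross(n, g);
      }
      rF[k] = F; rT[k] = T;
    }
  };
  rigid_net();

  auto wrapc = [&](double c) {
    return c - S.box * std::floor(c / S.box);
  };

  for (long step = 1; step <= nsteps; ++step) {
    auto tp0 = tick();
    // half kick + drift in one pass
    double guard2 = max_disp * max_disp;
    for (int i = 0; i < S.N; ++i) {
      if (bead_rigid[i] >= 0) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * S.fx[i]; S.vy[i] += h * S.fy[i]; S.vz[i] += h * S.fz[i];
      double dx = dt * S.vx[i], dy = dt * S.vy[i], dz = dt * S.vz[i];
      if (dx*dx + dy*dy + dz*dz > guard2)
        stop("integration blow-up: bead %d moved more than 0.5 sigma in one step (step %ld)", i + 1, step);
      S.ux[i] += dx; S.uy[i] += dy; S.uz[i] += dz;
      double cx = S.x[i] + dx, cy = S.y[i] + dy, cz = S.z[i] + dz;
      if (cx < 0) cx += S.box; else if (cx >= S.box) cx -= S.box;
      if (cy < 0) cy += S.box; else if (cy >= S.box) cy -= S.box;
      if (cz < 0) cz += S.box; else if (cz >= S.box) cz -= S.box;
      S.x[i] = cx; S.y[i] = cy; S.z[i] = cz;
    }
    for (size_t k = 0; k < rb.size(); ++k) {
      rb[k].vcom = rb[k].vcom + (0.5 * dt / rb[k].M) * rF[k];
      rb[k].L = rb[k].L + 0.5 * dt * rT[k];
    }
    for (size_t k = 0; k < rb.size(); ++k) {
      RigidBody &B = rb[k];
      B.com = B.com + dt * B.vcom;
      double R[3][3]; quat_to_mat(B.q, R);
      double Is[3][3], tmp[3][3], Ii[3][3];
      for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c)
        tmp[a][c] = R[a][0]*B.Ib[0][c] + R[a][1]*B.Ib[1][c] + R[a][2]*B.Ib[2][c];
      for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c)
        Is[a][c] = tmp[a][0]*R[c][0] + tmp[a][1]*R[c][1] + tmp[a][2]*R[c][2];
      mat3_inv(Is, Ii);
      V3 om = mat_vec(Ii, B.L);
      // dq/dt = 0.5 * (0, omega) * q
      Quat q = B.q;
      Quat dq{
        -0.5 * (om.x*q.x + om.y*q.y + om.z*q.z),
         0.5 * (om.x*q.w + om.y*q.z - om.z*q.y),
         0.5 * (om.y*q.w + om.z*q.x - om.x*q.z),
         0.5 * (om.z*q.w + om.x*q.y - om.y*q.x)};
      q.w += dt * dq.w; q.x += dt * dq.x; q.y += dt * dq.y; q.z += dt * dq.z;
      double qn = std::sqrt(q.w*q.w + q.x*q.x + q.y*q.y + q.z*q.z);
      q.w /= qn; q.x /= qn; q.y /= qn; q.z /= qn;
      B.q = q;
      quat_to_mat(B.q, R);
      for (size_t t = 0; t < B.beads.size(); ++t) {
        int i = B.beads[t];
        V3 p = B.com + mat_vec(R, B.b[t]);
        S.ux[i] = p.x; S.uy[i] = p.y; S.uz[i] = p.z;
        S.x[i] = wrapc(p.x); S.y[i] = wrapc(p.y); S.z[i] = wrapc(p.z);
        V3 n = mat_vec(R, B.nb[t]);
        S.nx[i] = n.x; S.ny[i] = n.y; S.nz[i] = n.z;
        V3 v = B.vcom + cross(om, mat_vec(R, B.b[t]));
        S.vx[i] = v.x; S.vy[i] = v.y; S.vz[i] = v.z;
      }
    }

    if (profile) tock(tp0, t_kick);
    auto tp1 = tick();
    {
      bool rn = need_rebuild(S);
      bool rp = need_rebuild_pp(S);
      if (rn || rp) { build_lists(S, rn, rp); if (rn) ++n_rebuilds; }
    }
    if (profile) tock(tp1, t_rebuild);
    auto tp2 = tick();
    bool gn_step = !rb.empty() || ((step % thermo_every) == 0);
    compute_forces(S, gn_step);
    rigid_net();
    if (profile) tock(tp2, t_forces);

    // half kick
    for (int i = 0; i < S.N; ++i) {
      if (bead_rigid[i] >= 0) continue;
      double h = 0.5 * dt / S.mass[i];
      S.vx[i] += h * S.fx[i]; S.vy[i] += h * S.fy[i]; S.vz[i] += h * S.fz[i];
    }
    for (size_t k = 0; k < rb.size(); ++k) {
      rb[k].vcom = rb[k].vcom + (0.5 * dt / rb[k].M) * rF[k];
      rb[k].L = rb[k].L + 0.5 * dt * rT[k];
    }

    // Langevin kick (friction + fluctuation, per bead)
    auto tp3 = tick();
    bool thermo_now = gamma > 0.0 && (step % thermo_every == 0);
    if (thermo_now) {
      for (int i = 0; i < S.N; ++i) {
        if (bead_rigid[i] >= 0) continue;
        double m = S.mass[i];
        double a = gamma * dt_t / m;
        double sn = sq_noise / m;
        S.vx[i] += -a * S.vx[i] + sn * zig_normal(rng);
        S.vy[i] += -a * S.vy[i] + sn * zig_normal(rng);
        S.vz[i] += -a * S.vz[i] + sn * zig_normal(rng);
      }
      for (size_t k = 0; k < rb.size(); ++k) {
        RigidBody &B = rb[k];
        double R[3][3]; quat_to_mat(B.q, R);
        double Is[3][3], tmp[3][3], Ii[3][3];
        for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c)
          tmp[a][c] = R[a][0]*B.Ib[0][c] + R[a][1]*B.Ib[1][c] + R[a][2]*B.Ib[2][c];
        for (int a = 0; a < 3; ++a) for (int c = 0; c < 3; ++c)
          Is[a][c] = tmp[a][0]*R[c][0] + tmp[a][1]*R[c][1] + tmp[a][2]*R[c][2];
        mat3_inv(Is, Ii);
        V3 om = mat_vec(Ii, B.L);
        V3 Sxi = v3(0,0,0), Txi = v3(0,0,0);
        for (size_t t = 0; t < B.beads.size(); ++t) {
          V3 xi = v3(sq_noise * zig_normal(rng), sq_noise * zig_normal(rng),
                     sq_noise * zig_normal(rng));
          Sxi = Sxi + xi;
          Txi = Txi + cross(mat_vec(R, B.b[t]), xi);
        }
        double Nb = (double)B.beads.size();
        B.vcom = B.vcom + (1.0 / B.M) * ((-gamma * Nb * dt_t) * B.vcom + Sxi);
        V3 fric = mat_vec(Is, om);
        B.L = B.L + (-gamma * dt_t) * fric + Txi;
      }
    }

    if (profile) tock(tp3, t_thermo);
    auto tp4 = tick();
    // overdamped rotational update of shell-bead orientations
    if (step % thermo_every == 0) {
      for (int i = 0; i < S.N; ++i) {
        if (S.type[i] != 3 || bead_rigid[i] >= 0) continue;
        V3 n = v3(S.nx[i], S.ny[i], S.nz[i]);
        V3 g = v3(S.gx[i], S.gy[i], S.gz[i]);
        V3 gp = g - dot(g, n) * n;
        V3 upd = (dt_t / gamma_r) * gp;
        if (gamma > 0.0 && kT > 0.0) {
          V3 xi = v3(zig_normal(rng), zig_normal(rng), zig_normal(rng));
          V3 xp = xi - dot(xi, n) * n;
          upd = upd + sq_noise_r * xp;
        }
        n = n + upd;
        double nn = norm(n);
        S.nx[i] = n.x / nn; S.ny[i] = n.y / nn; S.nz[i] = n.z / nn;
      }
    }

    if (profile) tock(tp4, t_norm);
    auto tp5 = tick();
    if (step % out_every == 0) record(step / out_every, step * dt);
    if (profile) tock(tp5, t_rec);
  }
  if (profile)
    Rprintf("profile (us/step): kick+drift %.1f rebuild %.1f (%d rebuilds) forces %.1f thermo %.1f normals %.1f record %.1f\n",
            1e6 * t_kick / nsteps, 1e6 * t_rebuild / nsteps, n_rebuilds,
            1e6 * t_forces / nsteps, 1e6 * t_thermo / nsteps,
            1e6 * t_norm / nsteps, 1e6 * t_rec / nsteps);

  // final system state back to R
  NumericMatrix pos(S.N, 3), vel(S.N, 3), nor(S.N, 3), unwr(S.N, 3);
  for (int i = 0; i < S.N; ++i) {
    pos(i,0) = S.x[i]; pos(i,1) = S.y[i]; pos(i,2) = S.z[i];
    vel(i,0) = S.vx[i]; vel(i,1) = S.vy[i]; vel(i,2) = S.vz[i];
    unwr(i,0) = S.ux[i]; unwr(i,1) = S.uy[i]; unwr(i,2) = S.uz[i];
    if (S.type[i] == 3) { nor(i,0) = S.nx[i]; nor(i,1) = S.ny[i]; nor(i,2) = S.nz[i]; }
    else { nor(i,0) = NA_REAL; nor(i,1) = NA_REAL; nor(i,2) = NA_REAL; }
  }
  wr.attr("dim") = IntegerVector::create(nframes, S.N, 3);
  uw.attr("dim") = IntegerVector::create(nframes, S.N, 3);
  nrm.attr("dim") = IntegerVector::create(nframes, Nnp, 3);
  cen.attr("dim") = IntegerVector::create(nframes, std::max(S.n_np,1), 3);
  return List::create(
    _["times"] = times, _["wrapped"] = wr, _["unwrapped"] = uw,
    _["normals"] = nrm, _["np_bead_index"] = wrap(npb),
    _["centroids"] = cen,
    _["potential"] = pe_v, _["kinetic"] = ke_v, _["kinetic_temperature"] = tk_v,
    _["final_positions"] = pos, _["final_velocities"] = vel,
    _["final_normals"] = nor, _["final_unwrapped"] = unwr);
}

// ---------------------------------------------------------------------------
// Contact counting: per frame and per NP, number of shell beads with at least
// one polymer/node bead within `cutoff` under minimum image.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix contact_counts_cpp(NumericVector frames, IntegerVector type,
                                 IntegerVector npid, int n_np, double box,
                                 double cutoff, bool pair_count) {
  IntegerVector dim = frames.attr("dim");
  int F = dim[0], N = dim[1];
  std::vector<int> poly, shell;
  for (int i = 0; i < N; ++i) {
    if (type[i] == 3) shell.push_back(i); else poly.push_back(i);
  }
  IntegerMatrix out(F, n_np);
  double c2 = cutoff * cutoff;
  for (int f = 0; f < F; ++f) {
    for (int si : shell) {
      double sx = frames[f + (long)F * (si + (long)N * 0)];
      double sy = frames[f + (long)F * (si + (long)N * 1)];
      double sz = frames[f + (long)F * (si + (long)N * 2)];
      int hits = 0;
      for (int pi : poly) {
        double dx = mimg(sx - frames[f + (long)F * (pi + (long)N * 0)], box);
        if (std::fabs(dx) > cutoff) continue;
        double dy = mimg(sy - frames[f + (long)F * (pi + (long)N * 1)], box);
        if (std::fabs(dy) > cutoff) continue;
        double dz = mimg(sz - frames[f + (long)F * (pi + (long)N * 2)], box);
        if (dx*dx + dy*dy + dz*dz < c2) {
          ++hits;
          if (!pair_count) break;
        }
      }
      if (hits > 0) out(f, npid[si] - 1) += pair_count ? hits : 1;
    }
  }
  return out;
}
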