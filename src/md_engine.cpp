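// Core numerical kernels: flexible three-site water force field
// (intramolecular power series + Ewald Coulomb + Buckingham short range,
// shifted-force truncation), velocity-Verlet NVE integrator with
// annealing-stage velocity rescaling, molecule-pair interaction energies,
// and pair-distance histograms for radial distribution functions.
//
// Units: nm, fs, u (g/mol), kJ/mol, elementary charge, K.
// 1 kJ/mol = 1e-6 u nm^2 fs^-2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EKJ = 1e-6;            // kJ/mol -> u nm^2/fs^2
static const double KB = 0.0083144621;     // kJ/(mol K)
static const double FCOUL = 138.935458;    // kJ nm / (mol e^2)
static const double TWO_OVER_SQRTPI = 1.1283791670955126;

struct ForceField {
  double re, th_e;                 // nm, rad
  double kr, kth, krr, krth, kr3, kr4;
  double A[3], b[3], C6[3];        // 0=OO, 1=OH, 2=HH
  double D[3], r0[3], gw[3];       // Gaussian well: -D exp(-gw (r - r0)^2)
  double alpha, rcut;              // nm^-1, nm
  int kmax2;
  // precomputed shifted-force constants
  double g_rc, dg_rc;              // erfc(alpha r)/r and derivative at rcut
  double u_rc[3], du_rc[3];        // short-range terms at rcut per pair type
};

static inline int pair_type(int ti, int tj) {
  // site type: 0 = O, 1 = H
  return ti + tj;  // 0: OO, 1: OH, 2: HH
}

static ForceField unpack_ff(const List& pp) {
  ForceField ff;
  ff.re = as<double>(pp["r_e"]);
  ff.th_e = as<double>(pp["theta_e_rad"]);
  ff.kr = as<double>(pp["k_r"]);
  ff.kth = as<double>(pp["k_theta"]);
  ff.krr = as<double>(pp["k_rr"]);
  ff.krth = as<double>(pp["k_rtheta"]);
  ff.kr3 = as<double>(pp["k_r3"]);
  ff.kr4 = as<double>(pp["k_r4"]);
  NumericVector A = pp["buck_A"], b = pp["buck_b"], C6 = pp["buck_C6"];
  NumericVector D = pp["hbond_D"], r0 = pp["hbond_r0"], gw = pp["hbond_gamma"];
  for (int t = 0; t < 3; ++t) {
    ff.A[t] = A[t]; ff.b[t] = b[t]; ff.C6[t] = C6[t];
    ff.D[t] = D[t]; ff.r0[t] = r0[t]; ff.gw[t] = gw[t];
  }
  ff.alpha = as<double>(pp["ewald_alpha"]);
  ff.rcut = as<double>(pp["r_cut"]);
  ff.kmax2 = as<int>(pp["kmax2"]);
  double rc = ff.rcut, a = ff.alpha;
  double erfc_rc = std::erfc(a * rc);
  ff.g_rc = erfc_rc / rc;
  ff.dg_rc = -(erfc_rc / (rc * rc) + TWO_OVER_SQRTPI * a * std::exp(-a * a * rc * rc) / rc);
  for (int t = 0; t < 3; ++t) {
    double ex = ff.A[t] * std::exp(-ff.b[t] * rc);
    double disp = ff.C6[t] / std::pow(rc, 6);
    double gb = ff.D[t] != 0.0 ? ff.D[t] * std::exp(-ff.gw[t] * (rc - ff.r0[t]) * (rc - ff.r0[t])) : 0.0;
    ff.u_rc[t] = ex - disp - gb;
    ff.du_rc[t] = -ff.b[t] * ex + 6.0 * disp / rc + 2.0 * ff.gw[t] * (rc - ff.r0[t]) * gb;
  }
  return ff;
}

static inline void min_image(double* d, double L) {
  for (int k = 0; k < 3; ++k) d[k] -= L * std::floor(d[k] / L + 0.5);
}

// reciprocal-space vectors (half space), grouped by (hx, hy) so the
// xy-phase product is computed once per group; built once per system
struct KVectors {
  struct Group { int hx, hy; std::vector<int> hz; std::vector<double> Ak; };
  std::vector<Group> groups;
  int hmax;
};

static KVectors build_kvectors(double L, const ForceField& ff) {
  KVectors kv;
  kv.hmax = (int)std::floor(std::sqrt((double)ff.kmax2)) ;
  double V = L * L * L;
  double twopiL = 2.0 * M_PI / L;
  for (int x = 0; x <= kv.hmax; ++x)
    for (int y = (x == 0 ? 0 : -kv.hmax); y <= kv.hmax; ++y) {
      KVectors::Group g; g.hx = x; g.hy = y;
      for (int z = ((x == 0 && y == 0) ? 1 : -kv.hmax); z <= kv.hmax; ++z) {
        int h2 = x * x + y * y + z * z;
        if (h2 == 0 || h2 > ff.kmax2) continue;
        double k2 = twopiL * twopiL * h2;
        g.hz.push_back(z);
        g.Ak.push_back(4.0 * M_PI * FCOUL / V * std::exp(-k2 / (4.0 * ff.alpha * ff.alpha)) / k2);
      }
      if (!g.hz.empty()) kv.groups.push_back(g);
    }
  return kv;
}

struct EnergyDecomp {
  double intra, real, recip, selfexcl, shortrange;
  double total() const { return intra + real + recip + selfexcl + shortrange; }
};

// scratch buffers reused across force calls; phase tables are stored
// row-contiguous over sites: x rows h = 0..hmax, y/z rows h = -hmax..hmax
struct Scratch {
  std::vector<double> exr, exi;        // (hmax+1) x n
  std::vector<double> eyr, eyi, ezr, ezi;  // (2*hmax+1) x n
  std::vector<double> axyr, axyi;      // q_i * xy phase, n
  std::vector<double> fx, fy, fz;      // reciprocal-space force accumulators
};

static void compute_forces(const double* pos, const double* q, const int* stype,
                           int n, double L, const ForceField& ff, const KVectors& kv,
                           Scratch& sc, double* F, EnergyDecomp& E) {
  for (int i = 0; i < 3 * n; ++i) F[i] = 0.0;
  E.intra = E.real = E.recip = E.selfexcl = E.shortrange = 0.0;
  const int nmol = n / 3;
  const double a = ff.alpha;
  const double rc = ff.rcut, rc2 = rc * rc;

  // ---- intramolecular valence terms + Ewald exclusion corrections ----
  for (int m = 0; m < nmol; ++m) {
    int iO = 3 * m, iH1 = 3 * m + 1, iH2 = 3 * m + 2;
    double d1[3], d2[3];
    for (int k = 0; k < 3; ++k) d1[k] = pos[3 * iH1 + k] - pos[3 * iO + k];
    for (int k = 0; k < 3; ++k) d2[k] = pos[3 * iH2 + k] - pos[3 * iO + k];
    min_image(d1, L); min_image(d2, L);
    double r1 = std::sqrt(d1[0]*d1[0] + d1[1]*d1[1] + d1[2]*d1[2]);
    double r2 = std::sqrt(d2[0]*d2[0] + d2[1]*d2[1] + d2[2]*d2[2]);
    if (r1 < 1e-4 || r2 < 1e-4) stop("overlapping O-H sites in molecule %d", m + 1);
    double u1[3], u2[3];
    for (int k = 0; k < 3; ++k) { u1[k] = d1[k] / r1; u2[k] = d2[k] / r2; }
    double cth = u1[0]*u2[0] + u1[1]*u2[1] + u1[2]*u2[2];
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
    double s1 = r1 - ff.re, s2 = r2 - ff.re, st = th - ff.th_e;
    E.intra += 0.5 * ff.kr * (s1 * s1 + s2 * s2)
             + ff.kr3 * (s1 * s1 * s1 + s2 * s2 * s2)
             + ff.kr4 * (s1 * s1 * s1 * s1 + s2 * s2 * s2 * s2)
             + 0.5 * ff.kth * st * st
             + ff.krr * s1 * s2
             + ff.krth * (s1 + s2) * st;
    double dVds1 = ff.kr * s1 + 3.0 * ff.kr3 * s1 * s1 + 4.0 * ff.kr4 * s1 * s1 * s1
                 + ff.krr * s2 + ff.krth * st;
    double dVds2 = ff.kr * s2 + 3.0 * ff.kr3 * s2 * s2 + 4.0 * ff.kr4 * s2 * s2 * s2
                 + ff.krr * s1 + ff.krth * st;
    double dVdth = ff.kth * st + ff.krth * (s1 + s2);
    for (int k = 0; k < 3; ++k) {
      // stretch gradients
      double f1 = -dVds1 * u1[k];
      double f2 = -dVds2 * u2[k];
      // angle gradients: dth/drH1 = (cth*u1 - u2)/(r1*sth)
      double p1 = (cth * u1[k] - u2[k]) / (r1 * sth);
      double p2 = (cth * u2[k] - u1[k]) / (r2 * sth);
      f1 += -dVdth * p1;
      f2 += -dVdth * p2;
      F[3 * iH1 + k] += f1;
      F[3 * iH2 + k] += f2;
      F[3 * iO + k] -= f1 + f2;
    }
    // Ewald exclusion: subtract erf-screened Coulomb for the 3 intramolecular pairs
    int ids[3][2] = {{iO, iH1}, {iO, iH2}, {iH1, iH2}};
    for (int p = 0; p < 3; ++p) {
      int i = ids[p][0], j = ids[p][1];
      double d[3];
      for (int k = 0; k < 3; ++k) d[k] = pos[3 * j + k] - pos[3 * i + k];
      min_image(d, L);
      double r2d = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      double r = std::sqrt(r2d);
      double qq = FCOUL * q[i] * q[j];
      double erf_r = 1.0 - std::erfc(a * r);
      E.selfexcl -= qq * erf_r / r;
      // force from -qq*erf(ar)/r ; d/dr = -qq*( (2a/sqrt(pi)) e^{-a^2 r^2}/r - erf(ar)/r^2 )
      double dudr = -qq * (TWO_OVER_SQRTPI * a * std::exp(-a * a * r2d) / r - erf_r / r2d);
      double fr = -dudr / r;
      for (int k = 0; k < 3; ++k) {
        F[3 * j + k] += fr * d[k];
        F[3 * i + k] -= fr * d[k];
      }
    }
  }

  // ---- Ewald self energy (constant) ----
  double sumq2 = 0.0;
  for (int i = 0; i < n; ++i) sumq2 += q[i] * q[i];
  E.selfexcl -= FCOUL * a / std::sqrt(M_PI) * sumq2;

  // ---- real space: shifted-force erfc Coulomb + shifted-force Buckingham ----
  const double invL = 1.0 / L;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = pos[3*i], yi = pos[3*i+1], zi = pos[3*i+2];
    const int mi = i / 3, ti = stype[i];
    for (int j = i + 1; j < n; ++j) {
      if (j / 3 == mi) continue;  // intramolecular pairs excluded
      double d[3] = {pos[3*j] - xi, pos[3*j+1] - yi, pos[3*j+2] - zi};
      d[0] -= L * std::nearbyint(d[0] * invL);
      d[1] -= L * std::nearbyint(d[1] * invL);
      d[2] -= L * std::nearbyint(d[2] * invL);
      double r2d = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
      if (r2d >= rc2) continue;
      double r = std::sqrt(r2d);
      if (r < 1e-4) stop("overlapping sites %d and %d", i + 1, j + 1);
      int t = pair_type(ti, stype[j]);
      double qq = FCOUL * q[i] * q[j];
      double erfc_r = std::erfc(a * r);
      double g = erfc_r / r;
      double dg = -(erfc_r / r2d + TWO_OVER_SQRTPI * a * std::exp(-a * a * r2d) / r);
      E.real += qq * (g - ff.g_rc - (r - rc) * ff.dg_rc);
      double dudr = qq * (dg - ff.dg_rc);
      // Buckingham + Gaussian H-bond well
      double ex = ff.A[t] * std::exp(-ff.b[t] * r);
      double disp = ff.C6[t] / (r2d * r2d * r2d);
      double usr = ex - disp, dusr = -ff.b[t] * ex + 6.0 * disp / r;
      if (ff.D[t] != 0.0) {
        double dr = r - ff.r0[t];
        double gb = ff.D[t] * std::exp(-ff.gw[t] * dr * dr);
        usr -= gb;
        dusr += 2.0 * ff.gw[t] * dr * gb;
      }
      E.shortrange += usr - ff.u_rc[t] - (r - rc) * ff.du_rc[t];
      dudr += dusr - ff.du_rc[t];
      double fr = -dudr / r;
      for (int k = 0; k < 3; ++k) {
        F[3 * j + k] += fr * d[k];
        F[3 * i + k] -= fr * d[k];
      }
    }
  }

  // ---- reciprocal space ----
  const int hmax = kv.hmax, nyz = 2 * hmax + 1;
  const double twopiL = 2.0 * M_PI / L;
  if ((int)sc.axyr.size() < n) {
    sc.exr.resize((size_t)(hmax + 1) * n); sc.exi.resize((size_t)(hmax + 1) * n);
    sc.eyr.resize((size_t)nyz * n); sc.eyi.resize((size_t)nyz * n);
    sc.ezr.resize((size_t)nyz * n); sc.ezi.resize((size_t)nyz * n);
    sc.axyr.resize(n); sc.axyi.resize(n);
    sc.fx.resize(n); sc.fy.resize(n); sc.fz.resize(n);
  }
  for (int i = 0; i < n; ++i) {
    double cx = std::cos(twopiL * pos[3*i]),   sx = std::sin(twopiL * pos[3*i]);
    double cy = std::cos(twopiL * pos[3*i+1]), sy = std::sin(twopiL * pos[3*i+1]);
    double cz = std::cos(twopiL * pos[3*i+2]), sz = std::sin(twopiL * pos[3*i+2]);
    sc.exr[i] = 1.0; sc.exi[i] = 0.0;
    for (int h = 1; h <= hmax; ++h) {
      sc.exr[(size_t)h*n + i] = sc.exr[(size_t)(h-1)*n + i] * cx - sc.exi[(size_t)(h-1)*n + i] * sx;
      sc.exi[(size_t)h*n + i] = sc.exr[(size_t)(h-1)*n + i] * sx + sc.exi[(size_t)(h-1)*n + i] * cx;
    }
    size_t o0 = (size_t)hmax * n;  // row for h = 0
    sc.eyr[o0 + i] = 1.0; sc.eyi[o0 + i] = 0.0;
    sc.ezr[o0 + i] = 1.0; sc.ezi[o0 + i] = 0.0;
    for (int h = 1; h <= hmax; ++h) {
      size_t op = o0 + (size_t)h * n, om = o0 - (size_t)h * n, opp = o0 + (size_t)(h-1) * n;
      sc.eyr[op + i] = sc.eyr[opp + i] * cy - sc.eyi[opp + i] * sy;
      sc.eyi[op + i] = sc.eyr[opp + i] * sy + sc.eyi[opp + i] * cy;
      sc.eyr[om + i] = sc.eyr[op + i];  sc.eyi[om + i] = -sc.eyi[op + i];
      sc.ezr[op + i] = sc.ezr[opp + i] * cz - sc.ezi[opp + i] * sz;
      sc.ezi[op + i] = sc.ezr[opp + i] * sz + sc.ezi[opp + i] * cz;
      sc.ezr[om + i] = sc.ezr[op + i];  sc.ezi[om + i] = -sc.ezi[op + i];
    }
  }
  for (int i = 0; i < n; ++i) { sc.fx[i] = 0.0; sc.fy[i] = 0.0; sc.fz[i] = 0.0; }
  for (const auto& g : kv.groups) {
    const double* xr = &sc.exr[(size_t)g.hx * n];
    const double* xi = &sc.exi[(size_t)g.hx * n];
    const double* yr = &sc.eyr[(size_t)(g.hy + hmax) * n];
    const double* yi = &sc.eyi[(size_t)(g.hy + hmax) * n];
    double* axyr = sc.axyr.data(); double* axyi = sc.axyi.data();
    for (int i = 0; i < n; ++i) {
      axyr[i] = q[i] * (xr[i] * yr[i] - xi[i] * yi[i]);
      axyi[i] = q[i] * (xr[i] * yi[i] + xi[i] * yr[i]);
    }
    for (size_t zz = 0; zz < g.hz.size(); ++zz) {
      int hz = g.hz[zz];
      const double* zr = &sc.ezr[(size_t)(hz + hmax) * n];
      const double* zi = &sc.ezi[(size_t)(hz + hmax) * n];
      double Sr = 0.0, Si = 0.0;
      for (int i = 0; i < n; ++i) {
        Sr += axyr[i] * zr[i] - axyi[i] * zi[i];
        Si += axyr[i] * zi[i] + axyi[i] * zr[i];
      }
      double Ak = g.Ak[zz];
      E.recip += Ak * (Sr * Sr + Si * Si);
      double kx = twopiL * g.hx, ky = twopiL * g.hy, kz = twopiL * hz;
      double cr = -2.0 * Ak * Si, ci = 2.0 * Ak * Sr;
      for (int i = 0; i < n; ++i) {
        // w = 2 Ak Im((a_i z_i) conj(S)) = cr * Re(a z) + ci * Im(a z)
        double er = axyr[i] * zr[i] - axyi[i] * zi[i];
        double ei = axyr[i] * zi[i] + axyi[i] * zr[i];
        double w = cr * er + ci * ei;
        sc.fx[i] += w * kx; sc.fy[i] += w * ky; sc.fz[i] += w * kz;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    F[3*i] += sc.fx[i]; F[3*i+1] += sc.fy[i]; F[3*i+2] += sc.fz[i];
  }
}

static void fill_stype(std::vector<int>& stype, int n) {
  stype.resize(n);
  for (int i = 0; i < n; ++i) stype[i] = (i % 3 == 0) ? 0 : 1;
}

// [[Rcpp::export(".cpp_forces")]]
List cpp_forces(NumericMatrix pos, NumericVector q, List pp, double L) {
  int n = pos.nrow();
  if (n % 3 != 0) stop("site count must be a multiple of 3");
  ForceField ff = unpack_ff(pp);
  if (ff.rcut >= L / 2 + 1e-12) stop("cutoff must be < L/2");
  KVectors kv = build_kvectors(L, ff);
  Scratch sc;
  std::vector<double> p(3 * n), F(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) p[3*i+k] = pos(i, k);
  std::vector<int> stype; fill_stype(stype, n);
  EnergyDecomp E;
  compute_forces(p.data(), REAL(q), stype.data(), n, L, ff, kv, sc, F.data(), E);
  NumericMatrix Fout(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) Fout(i, k) = F[3*i+k];
  return List::create(
    _["forces"] = Fout,
    _["energy"] = List::create(
      _["intramolecular"] = E.intra,
      _["coulomb_real"] = E.real,
      _["coulomb_reciprocal"] = E.recip,
      _["self_exclusion"] = E.selfexcl,
      _["short_range"] = E.shortrange,
      _["potential"] = E.total()));
}

// Full unscreened molecule-pair interaction energies (Coulomb + Buckingham,
// no cutoff, minimum image): matrix n_mol x n_mol.
// [[Rcpp::export(".cpp_pair_energy_matrix")]]
NumericMatrix cpp_pair_energy_matrix(NumericMatrix pos, NumericVector q, List pp, double L) {
  int n = pos.nrow();
  if (n % 3 != 0) stop("site count must be a multiple of 3");
  int nmol = n / 3;
  ForceField ff = unpack_ff(pp);
  std::vector<int> stype; fill_stype(stype, n);
  NumericMatrix out(nmol, nmol);
  for (int mi = 0; mi < nmol - 1; ++mi)
    for (int mj = mi + 1; mj < nmol; ++mj) {
      double e = 0.0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          int i = 3 * mi + a, j = 3 * mj + b;
          double d[3] = {pos(j,0) - pos(i,0), pos(j,1) - pos(i,1), pos(j,2) - pos(i,2)};
          min_image(d, L);
          double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
          if (r < 1e-4) stop("overlapping sites in molecules %d and %d", mi + 1, mj + 1);
          int t = pair_type(stype[i], stype[j]);
          e += FCOUL * q[i] * q[j] / r + ff.A[t] * std::exp(-ff.b[t] * r) - ff.C6[t] / std::pow(r, 6);
          if (ff.D[t] != 0.0)
            e -= ff.D[t] * std::exp(-ff.gw[t] * (r - ff.r0[t]) * (r - ff.r0[t]));
        }
      out(mi, mj) = e;
      out(mj, mi) = e;
    }
  return out;
}

// NVE integration with optional annealing stages (velocity rescaling).
// anneal: matrix with columns (target_T, n_steps, rescale_every).
// integrator: 0 = velocity Verlet, 1 = 4th-order Yoshida composition of
// velocity-Verlet substeps (three force evaluations per step).
// [[Rcpp::export(".cpp_run_md")]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                NumericVector q, List pp, double L, double dt,
                NumericMatrix anneal, int n_production,
                int store_every, int energy_every, int integrator) {
  int n = pos0.nrow();
  if (n % 3 != 0) stop("site count must be a multiple of 3");
  ForceField ff = unpack_ff(pp);
  if (ff.rcut >= L / 2 + 1e-12) stop("cutoff must be < L/2");
  KVectors kv = build_kvectors(L, ff);
  Scratch sc;
  std::vector<int> stype; fill_stype(stype, n);
  std::vector<double> p(3*n), v(3*n), F(3*n), invm(n);
  for (int i = 0; i < n; ++i) {
    invm[i] = 1.0 / mass[i];
    for (int k = 0; k < 3; ++k) { p[3*i+k] = pos0(i,k); v[3*i+k] = vel0(i,k); }
  }
  int dof = 3 * n - 3;
  EnergyDecomp E;
  compute_forces(p.data(), REAL(q), stype.data(), n, L, ff, kv, sc, F.data(), E);

  auto kinetic = [&]() {
    double ke = 0.0;
    for (int i = 0; i < n; ++i)
      ke += 0.5 * mass[i] * (v[3*i]*v[3*i] + v[3*i+1]*v[3*i+1] + v[3*i+2]*v[3*i+2]);
    return ke / EKJ;  // kJ/mol
  };
  auto remove_momentum = [&]() {
    double ptot[3] = {0, 0, 0}, mtot = 0.0;
    for (int i = 0; i < n; ++i) {
      mtot += mass[i];
      for (int k = 0; k < 3; ++k) ptot[k] += mass[i] * v[3*i+k];
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3*i+k] -= ptot[k] / mtot;
  };
  auto vv_step = [&](double h) {
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        v[3*i+k] += 0.5 * h * F[3*i+k] * EKJ * invm[i];
        p[3*i+k] += h * v[3*i+k];
        p[3*i+k] -= L * std::floor(p[3*i+k] / L);
      }
    compute_forces(p.data(), REAL(q), stype.data(), n, L, ff, kv, sc, F.data(), E);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3*i+k] += 0.5 * h * F[3*i+k] * EKJ * invm[i];
  };
  // Yoshida (1990) 4th-order coefficients
  const double y_w1 = 1.0 / (2.0 - std::cbrt(2.0));
  const double y_w0 = 1.0 - 2.0 * y_w1;
  auto step_once = [&]() {
    if (integrator == 0) {
      vv_step(dt);
    } else {
      vv_step(y_w1 * dt);
      vv_step(y_w0 * dt);
      vv_step(y_w1 * dt);
    }
  };

  // ---- annealing / equilibration ----
  for (int s = 0; s < anneal.nrow(); ++s) {
    double Ttar = anneal(s, 0);
    int nst = (int)anneal(s, 1), resc = std::max(1, (int)anneal(s, 2));
    for (int st = 1; st <= nst; ++st) {
      step_once();
      if (st % resc == 0) {
        remove_momentum();
        double T = 2.0 * kinetic() / (dof * KB);
        if (T > 0) {
          double lam = std::sqrt(Ttar / T);
          for (int i = 0; i < 3 * n; ++i) v[i] *= lam;
        }
      }
      if (st % 1000 == 0) Rcpp::checkUserInterrupt();
    }
  }

  // ---- production (strict NVE) ----
  int nstore = n_production / store_every;
  int nenergy = n_production / energy_every + 1;
  NumericVector posout((R_xlen_t)n * 3 * nstore), velout((R_xlen_t)n * 3 * nstore);
  NumericVector times(nstore);
  NumericMatrix energy(nenergy, 6);  // step, time, Ekin, Epot, Etot, T
  double E0 = kinetic() + E.total();
  int istore = 0, ien = 0;
  auto record_energy = [&](int step) {
    double ke = kinetic(), pe = E.total();
    energy(ien, 0) = step;
    energy(ien, 1) = step * dt;
    energy(ien, 2) = ke;
    energy(ien, 3) = pe;
    energy(ien, 4) = ke + pe;
    energy(ien, 5) = 2.0 * ke / (dof * KB);
    ++ien;
  };
  record_energy(0);
  for (int st = 1; st <= n_production; ++st) {
    step_once();
    if (st % store_every == 0 && istore < nstore) {
      R_xlen_t off = (R_xlen_t)istore * 3 * n;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          posout[off + i + (R_xlen_t)k * n] = p[3*i+k];
          velout[off + i + (R_xlen_t)k * n] = v[3*i+k];
        }
      times[istore] = st * dt;
      ++istore;
    }
    if (st % energy_every == 0 && ien < nenergy) {
      record_energy(st);
      double Et = energy(ien - 1, 4);
      if (!std::isfinite(Et) || std::fabs(Et) > 10.0 * std::fabs(E0) + 1e4)
        stop("total energy diverged at production step %d", st);
    }
    if (st % 1000 == 0) Rcpp::checkUserInterrupt();
  }
  posout.attr("dim") = IntegerVector::create(n, 3, nstore);
  velout.attr("dim") = IntegerVector::create(n, 3, nstore);
  colnames(energy) = CharacterVector::create("step", "time_fs", "E_kin", "E_pot", "E_tot", "T_inst");
  return List::create(
    _["positions"] = posout, _["velocities"] = velout, _["times"] = times,
    _["energy"] = energy);
}

// Pair-distance histogram over frames for RDF computation.
// pos: array (n_sites, 3, n_frames); idx1, idx2: 0-based site indices;
// mode: 0 = all cross pairs excluding same molecule (intermolecular),
//       1 = only same-molecule pairs (intramolecular),
//       2 = unordered pairs within one index set (like species, i<j, excl. same molecule).
// [[Rcpp::export(".cpp_pair_hist")]]
NumericVector cpp_pair_hist(NumericVector pos, IntegerVector idx1, IntegerVector idx2,
                            int mode, double L, double bin_width, double r_max) {
  IntegerVector dim = pos.attr("dim");
  int n = dim[0], nf = dim[2];
  int nbins = (int)std::ceil(r_max / bin_width);
  NumericVector counts(nbins);
  const double* P = REAL(pos);
  for (int f = 0; f < nf; ++f) {
    const double* pf = P + (R_xlen_t)f * 3 * n;
    auto dist = [&](int i, int j) {
      double d[3] = {pf[j] - pf[i], pf[j + n] - pf[i + n], pf[j + 2*n] - pf[i + 2*n]};
      min_image(d, L);
      return std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    };
    if (mode == 2) {
      for (int a = 0; a < idx1.size() - 1; ++a)
        for (int b = a + 1; b < idx1.size(); ++b) {
          int i = idx1[a], j = idx1[b];
          if (i / 3 == j / 3) continue;
          double r = dist(i, j);
          if (r < r_max) counts[(int)(r / bin_width)] += 1.0;
        }
    } else {
      for (int a = 0; a < idx1.size(); ++a)
        for (int b = 0; b < idx2.size(); ++b) {
          int i = idx1[a], j = idx2[b];
          bool same = (i / 3 == j / 3);
          if ((mode == 0 && same) || (mode == 1 && !same)) continue;
          double r = dist(i, j);
          if (r < r_max) counts[(int)(r / bin_width)] += 1.0;
        }
    }
    if (f % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
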