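// Compiled core: surrogate potential, restraint penalties with replica
// averaging, and the NVE/Langevin integrator loop.  Mirrors the R-level
// reference implementations (restraints.R, averaging.R), which the test
// suite cross-checks against this code and against finite differences.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double ACCEL_CONV = 4.184e-4;  // (kcal/mol/A)/amu -> A/fs^2
static const double KB = 1.987204e-3;       // kcal/(mol K)

struct Vec3 {
  double x, y, z;
  Vec3(double a = 0, double b = 0, double c = 0) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  Vec3 cross(const Vec3& o) const {
    return Vec3(y * o.z - z * o.y, z * o.x - x * o.z, x * o.y - y * o.x);
  }
  double norm() const { return std::sqrt(dot(*this)); }
};

struct Pot {
  double k_bond, d0, k_theta, theta0, eps_rep, r_rep;
  std::vector<double> c1, c2;  // torsional coefficients, scalar or per-dihedral
  bool has_tor;
  double tor(const std::vector<double>& v, int i) const {
    return v[(int)v.size() > 1 ? i : 0];
  }
};

static Pot parse_pot(const List& cfg) {
  Pot p;
  p.k_bond = cfg["k_bond"]; p.d0 = cfg["d0"];
  p.k_theta = cfg["k_theta"]; p.theta0 = cfg["theta0"];
  p.eps_rep = cfg["eps_rep"]; p.r_rep = cfg["r_rep"];
  p.c1 = as<std::vector<double>>(cfg["tor_c1"]);
  p.c2 = as<std::vector<double>>(cfg["tor_c2"]);
  p.has_tor = false;
  for (double v : p.c1) if (v != 0) p.has_tor = true;
  for (double v : p.c2) if (v != 0) p.has_tor = true;
  return p;
}

struct Restr {
  int type;      // 0 = distance (CA-CA), 1 = theta, 2 = gamma
  int a, b;      // 0-based residue indices (a = first atom of the tuple)
  double lo, hi, A, sigma, kappa, m;
};

static inline double logcosh(double x) {
  double ax = std::fabs(x);
  return ax + std::log1p(std::exp(-2.0 * ax)) - M_LN2;
}

// flat-bottom distance penalty and derivative
static void vdist_ed(double d, const Restr& r, double& V, double& dV) {
  double x = (d < r.lo) ? d - r.lo : ((d > r.hi) ? d - r.hi : 0.0);
  if (x == 0.0) { V = 0.0; dV = 0.0; return; }
  double x3 = x * x * x, x4 = x3 * x;
  double s4 = r.sigma * r.sigma * r.sigma * r.sigma;
  double den = s4 + x4;
  double u = x4 / den, up = 4.0 * x3 * s4 / (den * den);
  double w = 1.0 + r.kappa * logcosh(x), wp = r.kappa * std::tanh(x);
  V = r.A * u * w;
  dV = r.A * (up * w + u * wp);
}

static inline double wrap_pi(double x) {
  // (x + pi) mod 2pi - pi with floor semantics (mirrors R's %%), -pi -> pi
  double y = (x + M_PI) - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI)) - M_PI;
  return (y == -M_PI) ? M_PI : y;
}

// flat-bottom angular penalty (continuous excess form, or printed form)
static void vang_ed(double x, const Restr& r, bool compat, double& V, double& dV) {
  double d = wrap_pi(x - 0.5 * (r.lo + r.hi));
  double h = 0.5 * (r.hi - r.lo);
  if (std::fabs(d) <= h) { V = 0.0; dV = 0.0; return; }
  if (compat) {
    V = r.A * d * d * d * d / 4.0;
    dV = r.A * d * d * d;
  } else {
    double e = std::fabs(d) - h;
    V = r.A * e * e * e * e / 4.0;
    dV = r.A * e * e * e * ((d > 0) ? 1.0 : -1.0);
  }
}

// observable value + gradient for restraint r on coordinates q (n x 3,
// row-contiguous as q[3*i + k]); grad gets up to 4 site gradients
struct ObsGrad {
  double y;
  int idx[4];
  Vec3 g[4];
  int nsite;
};

static inline Vec3 getv(const double* q, int i) {
  return Vec3(q[3 * i], q[3 * i + 1], q[3 * i + 2]);
}

static void observe_one(const double* q, const Restr& r, ObsGrad& og,
                        bool need_grad) {
  if (r.type == 0) {
    Vec3 a = getv(q, r.a), b = getv(q, r.b);
    Vec3 dv = a - b;
    double d = dv.norm();
    og.y = d;
    og.nsite = 2;
    og.idx[0] = r.a; og.idx[1] = r.b;
    if (need_grad) {
      Vec3 u = dv * (1.0 / d);
      og.g[0] = u;
      og.g[1] = u * (-1.0);
    }
  } else if (r.type == 1) {
    Vec3 p1 = getv(q, r.a), p2 = getv(q, r.a + 1), p3 = getv(q, r.a + 2);
    Vec3 u = p1 - p2, v = p3 - p2;
    double lu = u.norm(), lv = v.norm();
    double cth = u.dot(v) / (lu * lv);
    if (cth > 1) cth = 1;
    if (cth < -1) cth = -1;
    og.y = std::acos(cth);
    og.nsite = 3;
    og.idx[0] = r.a; og.idx[1] = r.a + 1; og.idx[2] = r.a + 2;
    if (need_grad) {
      double sth = std::sqrt(1.0 - cth * cth);
      if (sth < 1e-10) sth = 1e-10;
      Vec3 g1 = (v * (1.0 / lv) - u * (cth / lu)) * (-1.0 / (lu * sth));
      Vec3 g3 = (u * (1.0 / lu) - v * (cth / lv)) * (-1.0 / (lv * sth));
      og.g[0] = g1;
      og.g[2] = g3;
      og.g[1] = (g1 + g3) * (-1.0);
    }
  } else {
    Vec3 p1 = getv(q, r.a), p2 = getv(q, r.a + 1);
    Vec3 p3 = getv(q, r.a + 2), p4 = getv(q, r.a + 3);
    Vec3 b1 = p2 - p1, b2 = p3 - p2, b3 = p4 - p3;
    Vec3 n1 = b1.cross(b2), n2 = b2.cross(b3);
    Vec3 m1 = n1.cross(n2);
    double lb2 = b2.norm();
    double g = std::atan2(m1.dot(b2) / lb2, n1.dot(n2));
    og.y = (g == -M_PI) ? M_PI : g;
    og.nsite = 4;
    og.idx[0] = r.a; og.idx[1] = r.a + 1;
    og.idx[2] = r.a + 2; og.idx[3] = r.a + 3;
    if (need_grad) {
      double n1sq = n1.dot(n1), n2sq = n2.dot(n2), b2sq = b2.dot(b2);
      Vec3 g1 = n1 * (-lb2 / n1sq);
      Vec3 g4 = n2 * (lb2 / n2sq);
      double t1 = -b1.dot(b2) / b2sq, t3 = -b3.dot(b2) / b2sq;
      og.g[0] = g1;
      og.g[3] = g4;
      og.g[1] = g1 * (t1 - 1.0) - g4 * t3;
      og.g[2] = g4 * (t3 - 1.0) - g1 * t1;
    }
  }
}

// surrogate potential: bonds + angles + optional torsion + repulsion;
// accumulates forces into f (not zeroed here), returns energy
static double surrogate_ef(const double* q, int n, const Pot& p, double* f) {
  double E = 0.0;
  for (int i = 0; i + 1 < n; ++i) {
    Vec3 dv = getv(q, i) - getv(q, i + 1);
    double d = dv.norm();
    double dd = d - p.d0;
    E += 0.5 * p.k_bond * dd * dd;
    double s = -p.k_bond * dd / d;
    f[3 * i] += s * dv.x;     f[3 * i + 1] += s * dv.y;     f[3 * i + 2] += s * dv.z;
    f[3 * (i + 1)] -= s * dv.x; f[3 * (i + 1) + 1] -= s * dv.y; f[3 * (i + 1) + 2] -= s * dv.z;
  }
  if (p.k_theta > 0) {
    Restr rr; rr.type = 1;
    for (int i = 0; i + 2 < n; ++i) {
      rr.a = i;
      ObsGrad og;
      observe_one(q, rr, og, true);
      double dth = og.y - p.theta0;
      E += 0.5 * p.k_theta * dth * dth;
      double dV = p.k_theta * dth;
      for (int k = 0; k < 3; ++k) {
        int j = og.idx[k];
        f[3 * j] -= dV * og.g[k].x;
        f[3 * j + 1] -= dV * og.g[k].y;
        f[3 * j + 2] -= dV * og.g[k].z;
      }
    }
  }
  if (p.has_tor) {
    Restr rr; rr.type = 2;
    for (int i = 0; i + 3 < n; ++i) {
      rr.a = i;
      ObsGrad og;
      observe_one(q, rr, og, true);
      double g = og.y;
      double c1 = p.tor(p.c1, i), c2 = p.tor(p.c2, i);
      E += c1 * (1.0 - std::cos(g)) + c2 * (1.0 - std::cos(2.0 * g));
      double dV = c1 * std::sin(g) + 2.0 * c2 * std::sin(2.0 * g);
      for (int k = 0; k < 4; ++k) {
        int j = og.idx[k];
        f[3 * j] -= dV * og.g[k].x;
        f[3 * j + 1] -= dV * og.g[k].y;
        f[3 * j + 2] -= dV * og.g[k].z;
      }
    }
  }
  if (p.eps_rep > 0) {
    double r2cut = p.r_rep * p.r_rep;
    for (int i = 0; i + 2 < n; ++i) {
      for (int j = i + 2; j < n; ++j) {
        Vec3 dv = getv(q, i) - getv(q, j);
        double r2 = dv.dot(dv);
        if (r2 >= r2cut) continue;
        double t = 1.0 - r2 / r2cut;
        E += p.eps_rep * t * t;
        // dV/dr = -4 eps r t / r_rep^2 ; force = -dV/dr * unit = +4 eps t/r2cut * dv
        double s = 4.0 * p.eps_rep * t / r2cut;
        f[3 * i] += s * dv.x;     f[3 * i + 1] += s * dv.y;     f[3 * i + 2] += s * dv.z;
        f[3 * j] -= s * dv.x;     f[3 * j + 1] -= s * dv.y;     f[3 * j + 2] -= s * dv.z;
      }
    }
  }
  return E;
}

// [[Rcpp::export]]
List surrogate_ef_cpp(NumericMatrix ca, List cfg) {
  int n = ca.nrow();
  Pot p = parse_pot(cfg);
  std::vector<double> q(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) q[3 * i + k] = ca(i, k);
  double E = surrogate_ef(q.data(), n, p, f.data());
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
  return List::create(_["energy"] = E, _["forces"] = F);
}

// frozen replica-averaging state
struct Frozen {
  std::vector<double> S;     // M x nr foreign power sums (dist/theta)
  std::vector<double> Ssin;  // M x nr foreign sine sums (gamma)
  std::vector<double> Scos;
};

static void full_update_core(const std::vector<double>& Q, int M, int n,
                             const std::vector<Restr>& rs, Frozen& fz) {
  int nr = (int)rs.size();
  std::vector<double> y(M * nr);
  ObsGrad og;
  for (int J = 0; J < M; ++J)
    for (int i = 0; i < nr; ++i) {
      observe_one(&Q[3 * n * J], rs[i], og, false);
      y[J * nr + i] = og.y;
    }
  for (int i = 0; i < nr; ++i) {
    if (rs[i].type == 2) {
      double ts = 0, tc = 0;
      for (int j = 0; j < M; ++j) {
        ts += std::sin(y[j * nr + i]);
        tc += std::cos(y[j * nr + i]);
      }
      for (int J = 0; J < M; ++J) {
        fz.Ssin[J * nr + i] = ts - std::sin(y[J * nr + i]);
        fz.Scos[J * nr + i] = tc - std::cos(y[J * nr + i]);
      }
    } else {
      double tot = 0;
      for (int j = 0; j < M; ++j) tot += std::pow(y[j * nr + i], -rs[i].m);
      for (int J = 0; J < M; ++J)
        fz.S[J * nr + i] = tot - std::pow(y[J * nr + i], -rs[i].m);
    }
  }
}

// restraint energy + forces for replica J; averaged = use frozen sums.
// Forces accumulated into f; returns unscaled penalty sum.
static double restraint_ef_core(const double* q, int n,
                                const std::vector<Restr>& rs,
                                bool averaged, int M, const Frozen* fz,
                                int J, bool compat, double* f) {
  double Vtot = 0.0;
  int nr = (int)rs.size();
  ObsGrad og;
  for (int i = 0; i < nr; ++i) {
    const Restr& r = rs[i];
    observe_one(q, r, og, true);
    double ybar, fac, V, dV;
    if (!averaged || M == 1) {
      ybar = og.y; fac = 1.0;
    } else if (r.type == 2) {
      double sbar = (fz->Ssin[J * nr + i] + std::sin(og.y)) / M;
      double cbar = (fz->Scos[J * nr + i] + std::cos(og.y)) / M;
      ybar = std::atan2(sbar, cbar);
      fac = (cbar * std::cos(og.y) + sbar * std::sin(og.y)) /
            (M * (sbar * sbar + cbar * cbar));
    } else {
      double own = std::pow(og.y, -r.m);
      ybar = std::pow((fz->S[J * nr + i] + own) / M, -1.0 / r.m);
      fac = (1.0 / M) * std::pow(ybar / og.y, r.m + 1.0);
    }
    if (r.type == 0) vdist_ed(ybar, r, V, dV);
    else vang_ed(ybar, r, compat, V, dV);
    Vtot += V;
    if (dV != 0.0) {
      double scale = -((averaged && M > 1) ? (double)M : 1.0) * dV * fac;
      for (int k = 0; k < og.nsite; ++k) {
        int s = og.idx[k];
        f[3 * s] += scale * og.g[k].x;
        f[3 * s + 1] += scale * og.g[k].y;
        f[3 * s + 2] += scale * og.g[k].z;
      }
    }
  }
  return Vtot;
}

static std::vector<Restr> parse_restraints(const NumericMatrix& rm) {
  std::vector<Restr> rs(rm.nrow());
  for (int i = 0; i < rm.nrow(); ++i) {
    rs[i].type = (int)rm(i, 0);
    rs[i].a = (int)rm(i, 1);
    rs[i].b = (int)rm(i, 2);
    rs[i].lo = rm(i, 3); rs[i].hi = rm(i, 4);
    rs[i].A = rm(i, 5); rs[i].sigma = rm(i, 6);
    rs[i].kappa = rm(i, 7); rs[i].m = rm(i, 8);
  }
  return rs;
}

// Joint integrator for M replicas sharing one averaging group.
// coords/vels: M x n x 3 flattened as replica-major [J][site][xyz].
// BAOAB Langevin splitting; friction = 0 reduces exactly to velocity
// Verlet (no noise is drawn).  Full averaging updates occur at global
// steps that are positive multiples of n_ave (activation at step n_ave);
// step_offset must be a multiple of n_ave.
// [[Rcpp::export]]
List md_run_core(NumericVector coords, NumericVector vels, int M, int n,
                 List cfg, NumericMatrix restr, double dt, int nsteps,
                 int n_ave, int n_snap, double friction, double temperature,
                 double mass, bool averaging, bool scale_energy, bool compat,
                 int step_offset, int log_every) {
  if (n_ave <= 0) stop("n_ave must be positive");
  if (step_offset % n_ave != 0) stop("step_offset must be a multiple of n_ave");
  Pot p = parse_pot(cfg);
  std::vector<Restr> rs = parse_restraints(restr);
  int nr = (int)rs.size();
  int nc = 3 * n;
  std::vector<double> Q(coords.begin(), coords.end());
  std::vector<double> V(vels.begin(), vels.end());
  if ((int)Q.size() != M * nc || (int)V.size() != M * nc)
    stop("coordinate/velocity size mismatch");
  Frozen fz;
  fz.S.assign(M * nr, 0.0);
  fz.Ssin.assign(M * nr, 0.0);
  fz.Scos.assign(M * nr, 0.0);
  bool avg_active = averaging && M > 1 && step_offset >= n_ave;
  if (avg_active) full_update_core(Q, M, n, rs, fz);

  std::vector<double> F(M * nc, 0.0), Epot(M, 0.0), Erest(M, 0.0);
  auto eval_forces = [&](int J) {
    std::fill(F.begin() + J * nc, F.begin() + (J + 1) * nc, 0.0);
    Epot[J] = surrogate_ef(&Q[J * nc], n, p, &F[J * nc]);
    Erest[J] = nr ? restraint_ef_core(&Q[J * nc], n, rs, avg_active, M, &fz,
                                      J, compat, &F[J * nc])
                  : 0.0;
  };
  for (int J = 0; J < M; ++J) eval_forces(J);

  bool thermo = friction > 0;
  double c1v = thermo ? std::exp(-friction * dt) : 1.0;
  double c2v = thermo ? std::sqrt((1.0 - c1v * c1v) * KB * temperature *
                                  ACCEL_CONV / mass)
                      : 0.0;
  double fscale = ACCEL_CONV / mass;  // force (kcal/mol/A) -> accel (A/fs^2)

  int nlog = (log_every > 0) ? (nsteps / log_every) : 0;
  NumericMatrix elog(nlog * M, 7);
  int logrow = 0;
  int nsnapout = (n_snap > 0) ? (nsteps / n_snap) : 0;
  // snapshots flattened [frame][replica][site][xyz]
  NumericVector snaps((R_xlen_t)nsnapout * M * nc);
  IntegerVector snap_steps(nsnapout);
  int snaprow = 0;

  for (int s = 1; s <= nsteps; ++s) {
    int g_prev = step_offset + s - 1;
    if (averaging && M > 1 && g_prev >= n_ave && g_prev % n_ave == 0) {
      full_update_core(Q, M, n, rs, fz);
      avg_active = true;
      for (int J = 0; J < M; ++J) eval_forces(J);
    }
    for (int J = 0; J < M; ++J) {
      double* q = &Q[J * nc];
      double* v = &V[J * nc];
      double* f = &F[J * nc];
      for (int k = 0; k < nc; ++k) v[k] += 0.5 * dt * f[k] * fscale;
      for (int k = 0; k < nc; ++k) q[k] += 0.5 * dt * v[k];
      if (thermo)
        for (int k = 0; k < nc; ++k) v[k] = c1v * v[k] + c2v * norm_rand();
      for (int k = 0; k < nc; ++k) q[k] += 0.5 * dt * v[k];
      eval_forces(J);
      for (int k = 0; k < nc; ++k) v[k] += 0.5 * dt * f[k] * fscale;
      for (int k = 0; k < nc; ++k)
        if (!std::isfinite(q[k]))
          stop("non-finite coordinate at step %d (replica %d)", g_prev + 1, J + 1);
    }
    int g = g_prev + 1;
    if (log_every > 0 && s % log_every == 0 && logrow < nlog) {
      for (int J = 0; J < M; ++J) {
        double ke = 0;
        for (int k = 0; k < nc; ++k) ke += V[J * nc + k] * V[J * nc + k];
        ke *= 0.5 * mass / ACCEL_CONV;
        // the conserved quantity carries M x the restraint term only while
        // averaging (and hence the M-fold force scaling) is active
        double er = (scale_energy && avg_active) ? M * Erest[J] : Erest[J];
        double tot = ke + Epot[J] + er;
        double tinst = 2.0 * ke / (nc * KB);
        elog(logrow * M + J, 0) = g;
        elog(logrow * M + J, 1) = J + 1;
        elog(logrow * M + J, 2) = ke;
        elog(logrow * M + J, 3) = Epot[J];
        elog(logrow * M + J, 4) = er;
        elog(logrow * M + J, 5) = tot;
        elog(logrow * M + J, 6) = tinst;
      }
      ++logrow;
    }
    if (n_snap > 0 && s % n_snap == 0 && snaprow < nsnapout) {
      for (int k = 0; k < M * nc; ++k)
        snaps[(R_xlen_t)snaprow * M * nc + k] = Q[k];
      snap_steps[snaprow] = g;
      ++snaprow;
    }
  }
  // final per-replica extended potential energy (surrogate + unscaled
  // restraint), used by the exchange criterion
  NumericVector epot_out(M), erest_out(M);
  for (int J = 0; J < M; ++J) {
    epot_out[J] = Epot[J];
    erest_out[J] = Erest[J];
  }
  return List::create(
      _["coords"] = NumericVector(Q.begin(), Q.end()),
      _["vels"] = NumericVector(V.begin(), V.end()),
      _["snapshots"] = snaps, _["snap_steps"] = snap_steps,
      _["energy_log"] = elog, _["e_pot"] = epot_out, _["e_restraint"] = erest_out);
}

// single-chain restraint energy/forces (non-averaged); used by the R-level
// minimizer for speed on CA-only restraint sets
// [[Rcpp::export]]
List restraint_ef_cpp(NumericMatrix ca, NumericMatrix restr, bool compat) {
  int n = ca.nrow();
  std::vector<Restr> rs = parse_restraints(restr);
  std::vector<double> q(3 * n), f(3 * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) q[3 * i + k] = ca(i, k);
  double E = rs.empty() ? 0.0
                        : restraint_ef_core(q.data(), n, rs, false, 1, nullptr,
                                            0, compat, f.data());
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
  return List::create(_["energy"] = E, _["forces"] = F);
}
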