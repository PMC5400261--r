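// Core numerics for the C-alpha structure-based model:
//   - potential energy terms of the Hamiltonian (bonds, angles, dihedrals,
//     12-10 native contacts, r^-12 excluded volume, Debye-Huckel) with
//     analytic gradients
//   - smooth (differentiable) fraction-of-native-contacts CV
//   - BAOAB Langevin integrator with optional umbrella / well-tempered
//     metadynamics bias, spherical confinement, and early stop on binding
//
// Lengths in nm, energies in epsilon (1 epsilon == 1 kJ/mol), time in tau,
// masses all 1.  Indices arriving from R are 1-based and shifted here.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_set>
#include <random>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
};

static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 scale(const Vec3& a, double s) {
  return {a.x * s, a.y * s, a.z * s};
}

struct Topology {
  int n;
  std::vector<int> chain;          // chain index per bead
  std::vector<double> charge;      // e units
  // bonds
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0;
  // angles
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_t0;
  // dihedrals
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_p0;
  // native pairs
  std::vector<int> p_i, p_j;
  std::vector<double> p_sig, p_eps;
  std::vector<int> p_inter;        // 1 if intermolecular
  // constants
  double bond_k, angle_k, kdih1, kdih3, eps_nc, sigma_nc;
  int idp_chain;                   // chain index of the disordered ligand
  // derived pair lists
  std::vector<std::pair<int, int>> ev_pairs;   // excluded-volume pairs
  std::vector<std::pair<int, int>> dh_pairs;   // charged pairs (not 1-2)
};

struct ElecParams {
  bool enabled;
  double gamma, kcoul, bkappa, kappa, dielectric;
};

static long long pkey(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * n + j;
}

static Topology parse_topology(const List& topo) {
  Topology T;
  NumericVector charge = topo["charges"];
  IntegerVector chain = topo["chain"];
  T.n = charge.size();
  T.charge.assign(charge.begin(), charge.end());
  T.chain.assign(chain.begin(), chain.end());

  NumericMatrix bonds = topo["bonds"];
  for (int r = 0; r < bonds.nrow(); ++r) {
    T.b_i.push_back((int)bonds(r, 0) - 1);
    T.b_j.push_back((int)bonds(r, 1) - 1);
    T.b_r0.push_back(bonds(r, 2));
  }
  NumericMatrix angles = topo["angles"];
  for (int r = 0; r < angles.nrow(); ++r) {
    T.a_i.push_back((int)angles(r, 0) - 1);
    T.a_j.push_back((int)angles(r, 1) - 1);
    T.a_k.push_back((int)angles(r, 2) - 1);
    T.a_t0.push_back(angles(r, 3));
  }
  NumericMatrix dih = topo["dihedrals"];
  for (int r = 0; r < dih.nrow(); ++r) {
    T.d_i.push_back((int)dih(r, 0) - 1);
    T.d_j.push_back((int)dih(r, 1) - 1);
    T.d_k.push_back((int)dih(r, 2) - 1);
    T.d_l.push_back((int)dih(r, 3) - 1);
    T.d_p0.push_back(dih(r, 4));
  }
  NumericMatrix pairs = topo["native_pairs"];
  for (int r = 0; r < pairs.nrow(); ++r) {
    T.p_i.push_back((int)pairs(r, 0) - 1);
    T.p_j.push_back((int)pairs(r, 1) - 1);
    T.p_sig.push_back(pairs(r, 2));
    T.p_eps.push_back(pairs(r, 3));
    T.p_inter.push_back((int)pairs(r, 4));
  }
  List cst = topo["constants"];
  T.bond_k = as<double>(cst["bond_k"]);
  T.angle_k = as<double>(cst["angle_k"]);
  T.kdih1 = as<double>(cst["kdih1"]);
  T.kdih3 = as<double>(cst["kdih3"]);
  T.eps_nc = as<double>(cst["eps_nc"]);
  T.sigma_nc = as<double>(cst["sigma_nc"]);
  T.idp_chain = as<int>(topo["idp_chain"]);

  // exclusion set: 1-2 bonds, 1-3 angle ends, native pairs
  std::unordered_set<long long> excl;
  for (size_t r = 0; r < T.b_i.size(); ++r)
    excl.insert(pkey(T.b_i[r], T.b_j[r], T.n));
  for (size_t r = 0; r < T.a_i.size(); ++r)
    excl.insert(pkey(T.a_i[r], T.a_k[r], T.n));
  std::unordered_set<long long> bonded12;
  for (size_t r = 0; r < T.b_i.size(); ++r)
    bonded12.insert(pkey(T.b_i[r], T.b_j[r], T.n));
  for (size_t r = 0; r < T.p_i.size(); ++r)
    excl.insert(pkey(T.p_i[r], T.p_j[r], T.n));

  for (int i = 0; i < T.n; ++i)
    for (int j = i + 1; j < T.n; ++j)
      if (!excl.count(pkey(i, j, T.n))) T.ev_pairs.push_back({i, j});

  for (int i = 0; i < T.n; ++i) {
    if (T.charge[i] == 0.0) continue;
    for (int j = i + 1; j < T.n; ++j) {
      if (T.charge[j] == 0.0) continue;
      if (bonded12.count(pkey(i, j, T.n))) continue;
      T.dh_pairs.push_back({i, j});
    }
  }
  return T;
}

static ElecParams parse_elec(const List& elec) {
  ElecParams E;
  E.enabled = as<bool>(elec["enabled"]);
  E.gamma = as<double>(elec["gamma_dh"]);
  E.kcoul = as<double>(elec["k_coulomb"]);
  E.bkappa = as<double>(elec["b_kappa"]);
  E.kappa = as<double>(elec["kappa"]);
  E.dielectric = as<double>(elec["dielectric"]);
  return E;
}

// Energy breakdown indices
enum { E_BOND = 0, E_ANGLE, E_DIH, E_CONTACT, E_EV, E_ELEC, E_NTERMS };

// Accumulate all Hamiltonian terms and their forces.
static void compute_forces(const std::vector<Vec3>& pos, const Topology& T,
                           const ElecParams& E, double* eterm,
                           std::vector<Vec3>& frc) {
  for (int t = 0; t < E_NTERMS; ++t) eterm[t] = 0.0;
  for (int i = 0; i < T.n; ++i) frc[i] = {0.0, 0.0, 0.0};

  // bonds: k (r - r0)^2
  for (size_t b = 0; b < T.b_i.size(); ++b) {
    int i = T.b_i[b], j = T.b_j[b];
    Vec3 d = sub(pos[i], pos[j]);
    double r = norm(d);
    double dr = r - T.b_r0[b];
    eterm[E_BOND] += T.bond_k * dr * dr;
    double f = -2.0 * T.bond_k * dr / r;
    frc[i].x += f * d.x; frc[i].y += f * d.y; frc[i].z += f * d.z;
    frc[j].x -= f * d.x; frc[j].y -= f * d.y; frc[j].z -= f * d.z;
  }

  // angles: k (theta - theta0)^2
  for (size_t a = 0; a < T.a_i.size(); ++a) {
    int i = T.a_i[a], j = T.a_j[a], k = T.a_k[a];
    Vec3 rij = sub(pos[i], pos[j]);
    Vec3 rkj = sub(pos[k], pos[j]);
    double nij = norm(rij), nkj = norm(rkj);
    double c = dot(rij, rkj) / (nij * nkj);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double s2 = 1.0 - c * c;
    if (s2 < 1e-12)
      stop("collinear angle triple at beads %d-%d-%d", i + 1, j + 1, k + 1);
    double s = std::sqrt(s2);
    double theta = std::acos(c);
    double dth = theta - T.a_t0[a];
    eterm[E_ANGLE] += T.angle_k * dth * dth;
    double dVdth = 2.0 * T.angle_k * dth;
    // dtheta/dri etc.
    double coef = dVdth / s;   // -dV/dcos(theta) * dcos/dr gives force below
    Vec3 di = scale(sub(scale(rkj, 1.0 / (nij * nkj)), scale(rij, c / (nij * nij))), coef);
    Vec3 dk = scale(sub(scale(rij, 1.0 / (nij * nkj)), scale(rkj, c / (nkj * nkj))), coef);
    frc[i].x += di.x; frc[i].y += di.y; frc[i].z += di.z;
    frc[k].x += dk.x; frc[k].y += dk.y; frc[k].z += dk.z;
    frc[j].x -= di.x + dk.x; frc[j].y -= di.y + dk.y; frc[j].z -= di.z + dk.z;
  }

  // dihedrals: sum_n K_n (1 - cos(n (phi - phi0))), n in {1, 3}
  for (size_t d = 0; d < T.d_i.size(); ++d) {
    int i = T.d_i[d], j = T.d_j[d], k = T.d_k[d], l = T.d_l[d];
    Vec3 rij = sub(pos[i], pos[j]);
    Vec3 rkj = sub(pos[k], pos[j]);
    Vec3 rkl = sub(pos[k], pos[l]);
    Vec3 m = cross(rij, rkj);
    Vec3 nv = cross(rkj, rkl);
    double nrkj = norm(rkj);
    double m2 = dot(m, m), n2 = dot(nv, nv);
    if (m2 < 1e-14 || n2 < 1e-14)
      stop("degenerate dihedral at beads %d-%d-%d-%d", i + 1, j + 1, k + 1, l + 1);
    double phi = std::atan2(dot(rij, nv) * nrkj, dot(m, nv));
    double dphi1 = phi - T.d_p0[d];
    eterm[E_DIH] += T.kdih1 * (1.0 - std::cos(dphi1)) +
                    T.kdih3 * (1.0 - std::cos(3.0 * dphi1));
    double dVdphi = T.kdih1 * std::sin(dphi1) +
                    3.0 * T.kdih3 * std::sin(3.0 * dphi1);
    // GROMACS-style force distribution
    Vec3 fi = scale(m, -dVdphi * nrkj / m2);
    Vec3 fl = scale(nv, dVdphi * nrkj / n2);
    double p = dot(rij, rkj) / (nrkj * nrkj);
    double q = dot(rkl, rkj) / (nrkj * nrkj);
    Vec3 sv = sub(scale(fi, p), scale(fl, q));
    Vec3 fj = sub(sv, fi);
    Vec3 fk = sub(scale(fl, -1.0), sv);
    frc[i].x += fi.x; frc[i].y += fi.y; frc[i].z += fi.z;
    frc[j].x += fj.x; frc[j].y += fj.y; frc[j].z += fj.z;
    frc[k].x += fk.x; frc[k].y += fk.y; frc[k].z += fk.z;
    frc[l].x += fl.x; frc[l].y += fl.y; frc[l].z += fl.z;
  }

  // native contacts: eps_ij [5 (sig/r)^12 - 6 (sig/r)^10]
  for (size_t p = 0; p < T.p_i.size(); ++p) {
    int i = T.p_i[p], j = T.p_j[p];
    Vec3 d = sub(pos[i], pos[j]);
    double r2 = dot(d, d);
    if (r2 < 1e-12) stop("overflowing contact pair %d-%d (r -> 0)", i + 1, j + 1);
    double s2 = T.p_sig[p] * T.p_sig[p] / r2;
    double s10 = s2 * s2 * s2 * s2 * s2;
    double s12 = s10 * s2;
    eterm[E_CONTACT] += T.p_eps[p] * (5.0 * s12 - 6.0 * s10);
    // dV/dr * (1/r) = eps (-60 s12 + 60 s10)/r2
    double f = -T.p_eps[p] * 60.0 * (s10 - s12) / r2;  // force = -dV/dr / r
    frc[i].x += f * d.x; frc[i].y += f * d.y; frc[i].z += f * d.z;
    frc[j].x -= f * d.x; frc[j].y -= f * d.y; frc[j].z -= f * d.z;
  }

  // excluded volume: eps_nc (sigma_nc / r)^12
  double snc2 = T.sigma_nc * T.sigma_nc;
  for (size_t p = 0; p < T.ev_pairs.size(); ++p) {
    int i = T.ev_pairs[p].first, j = T.ev_pairs[p].second;
    Vec3 d = sub(pos[i], pos[j]);
    double r2 = dot(d, d);
    if (r2 < 1e-12) stop("overflowing excluded-volume pair %d-%d", i + 1, j + 1);
    double s2 = snc2 / r2;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    eterm[E_EV] += T.eps_nc * s12;
    double f = 12.0 * T.eps_nc * s12 / r2;
    frc[i].x += f * d.x; frc[i].y += f * d.y; frc[i].z += f * d.z;
    frc[j].x -= f * d.x; frc[j].y -= f * d.y; frc[j].z -= f * d.z;
  }

  // Debye-Huckel electrostatics
  if (E.enabled) {
    double pref = E.gamma * E.kcoul * E.bkappa / E.dielectric;
    for (size_t p = 0; p < T.dh_pairs.size(); ++p) {
      int i = T.dh_pairs[p].first, j = T.dh_pairs[p].second;
      Vec3 d = sub(pos[i], pos[j]);
      double r = norm(d);
      if (r < 1e-6) stop("coincident charged beads %d-%d", i + 1, j + 1);
      double qq = T.charge[i] * T.charge[j];
      double ex = std::exp(-E.kappa * r);
      double v = pref * qq * ex / r;
      eterm[E_ELEC] += v;
      // dV/dr = -v (kappa + 1/r); force = -dV/dr * dhat
      double f = v * (E.kappa + 1.0 / r) / r;
      frc[i].x += f * d.x; frc[i].y += f * d.y; frc[i].z += f * d.z;
      frc[j].x -= f * d.x; frc[j].y -= f * d.y; frc[j].z -= f * d.z;
    }
  }
}

// smooth Q over a pair subset: Q = mean_i 1/(1 + exp(k (r - lambda sigma)))
static double smooth_q_internal(const std::vector<Vec3>& pos, const Topology& T,
                                bool inter_only, double k, double lambda,
                                std::vector<Vec3>* grad) {
  int nsel = 0;
  double qsum = 0.0;
  if (grad)
    for (int i = 0; i < T.n; ++i) (*grad)[i] = {0.0, 0.0, 0.0};
  for (size_t p = 0; p < T.p_i.size(); ++p) {
    if (inter_only && !T.p_inter[p]) continue;
    ++nsel;
  }
  if (nsel == 0) return 0.0;
  for (size_t p = 0; p < T.p_i.size(); ++p) {
    if (inter_only && !T.p_inter[p]) continue;
    int i = T.p_i[p], j = T.p_j[p];
    Vec3 d = sub(pos[i], pos[j]);
    double r = norm(d);
    double z = k * (r - lambda * T.p_sig[p]);
    double s;
    if (z > 0) {
      double e = std::exp(-z);
      s = e / (1.0 + e);
    } else {
      s = 1.0 / (1.0 + std::exp(z));
    }
    qsum += s;
    if (grad) {
      double dsdr = -k * s * (1.0 - s);
      double g = dsdr / (nsel * r);
      (*grad)[i].x += g * d.x; (*grad)[i].y += g * d.y; (*grad)[i].z += g * d.z;
      (*grad)[j].x -= g * d.x; (*grad)[j].y -= g * d.y; (*grad)[j].z -= g * d.z;
    }
  }
  return qsum / nsel;
}

// hard-cutoff Q (formed iff r < lambda sigma) over inter or IDP-intra pairs
static double hard_q(const std::vector<Vec3>& pos, const Topology& T,
                     bool inter, double lambda) {
  int nsel = 0, formed = 0;
  for (size_t p = 0; p < T.p_i.size(); ++p) {
    bool is_inter = T.p_inter[p] != 0;
    bool idp_intra = !is_inter && T.chain[T.p_i[p]] == T.idp_chain;
    if (inter ? !is_inter : !idp_intra) continue;
    ++nsel;
    Vec3 d = sub(pos[T.p_i[p]], pos[T.p_j[p]]);
    if (norm(d) < lambda * T.p_sig[p]) ++formed;
  }
  return nsel ? (double)formed / nsel : NA_REAL;
}

static double min_inter_dist(const std::vector<Vec3>& pos, const Topology& T) {
  double best = R_PosInf;
  for (int i = 0; i < T.n; ++i) {
    if (T.chain[i] == T.idp_chain) continue;
    for (int j = 0; j < T.n; ++j) {
      if (T.chain[j] != T.idp_chain) continue;
      double d = norm(sub(pos[i], pos[j]));
      if (d < best) best = d;
    }
  }
  return best;
}

static double ligand_rg(const std::vector<Vec3>& pos, const Topology& T) {
  double cx = 0, cy = 0, cz = 0;
  int n = 0;
  for (int i = 0; i < T.n; ++i)
    if (T.chain[i] == T.idp_chain) { cx += pos[i].x; cy += pos[i].y; cz += pos[i].z; ++n; }
  if (n < 2) return NA_REAL;
  cx /= n; cy /= n; cz /= n;
  double s = 0;
  for (int i = 0; i < T.n; ++i)
    if (T.chain[i] == T.idp_chain) {
      double dx = pos[i].x - cx, dy = pos[i].y - cy, dz = pos[i].z - cz;
      s += dx * dx + dy * dy + dz * dz;
    }
  return std::sqrt(s / n);
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix pos, List topo, List elec) {
  Topology T = parse_topology(topo);
  ElecParams E = parse_elec(elec);
  std::vector<Vec3> x(T.n), f(T.n);
  for (int i = 0; i < T.n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  double eterm[E_NTERMS];
  compute_forces(x, T, E, eterm, f);
  NumericVector terms = NumericVector::create(
      _["bond"] = eterm[E_BOND], _["angle"] = eterm[E_ANGLE],
      _["dihedral"] = eterm[E_DIH], _["contact"] = eterm[E_CONTACT],
      _["excluded_volume"] = eterm[E_EV], _["electrostatic"] = eterm[E_ELEC]);
  NumericMatrix frc(T.n, 3);
  for (int i = 0; i < T.n; ++i) {
    frc(i, 0) = f[i].x; frc(i, 1) = f[i].y; frc(i, 2) = f[i].z;
  }
  return List::create(_["terms"] = terms, _["forces"] = frc);
}

// [[Rcpp::export]]
List smooth_q_cpp(NumericMatrix pos, List topo, double steepness,
                  double lambda, bool inter_only) {
  Topology T = parse_topology(topo);
  std::vector<Vec3> x(T.n), g(T.n);
  for (int i = 0; i < T.n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  double q = smooth_q_internal(x, T, inter_only, steepness, lambda, &g);
  NumericMatrix grad(T.n, 3);
  for (int i = 0; i < T.n; ++i) {
    grad(i, 0) = g[i].x; grad(i, 1) = g[i].y; grad(i, 2) = g[i].z;
  }
  return List::create(_["q"] = q, _["gradient"] = grad);
}

// [[Rcpp::export]]
List hard_q_cpp(NumericMatrix pos, List topo, double lambda) {
  Topology T = parse_topology(topo);
  std::vector<Vec3> x(T.n);
  for (int i = 0; i < T.n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  return List::create(_["q_inter"] = hard_q(x, T, true, lambda),
                      _["q_intra"] = hard_q(x, T, false, lambda));
}

struct BiasState {
  int type;          // 0 none, 1 umbrella, 2 WTM
  int cv_type;       // 0 smooth Q_inter, 1 x coordinate of cv_bead
  int cv_bead;
  double cv_k, cv_lambda;
  double umb_k, umb_c;
  double wtm_h0, wtm_sigma, wtm_bf, kT;
  int wtm_stride;
  std::vector<double> centers, heights, times;
  // tabulated bias on a uniform CV grid (linear interpolation); the exact
  // Gaussian ledger is still returned for analysis-side reconstruction
  double grid_min, grid_max, grid_dx;
  int ngrid;
  std::vector<double> vgrid;

  void init_grid(double lo, double hi, int n) {
    grid_min = lo; grid_max = hi; ngrid = n;
    grid_dx = (hi - lo) / (n - 1);
    vgrid.assign(n, 0.0);
  }
  void deposit(double c, double h) {
    int lo = (int)std::floor((c - 6.0 * wtm_sigma - grid_min) / grid_dx);
    int hi = (int)std::ceil((c + 6.0 * wtm_sigma - grid_min) / grid_dx);
    if (lo < 0) lo = 0;
    if (hi > ngrid - 1) hi = ngrid - 1;
    for (int g = lo; g <= hi; ++g) {
      double d = grid_min + g * grid_dx - c;
      vgrid[g] += h * std::exp(-d * d / (2.0 * wtm_sigma * wtm_sigma));
    }
  }
  double bias_value(double cv) const {
    if (type == 1) {
      double d = cv - umb_c;
      return 0.5 * umb_k * d * d;
    }
    if (cv <= grid_min) return vgrid.front();
    if (cv >= grid_max) return vgrid.back();
    double u = (cv - grid_min) / grid_dx;
    int g = (int)u;
    double frac = u - g;
    return vgrid[g] * (1.0 - frac) + vgrid[g + 1] * frac;
  }
  double bias_deriv(double cv) const {
    if (type == 1) return umb_k * (cv - umb_c);
    if (cv <= grid_min || cv >= grid_max) return 0.0;
    int g = (int)((cv - grid_min) / grid_dx);
    return (vgrid[g + 1] - vgrid[g]) / grid_dx;
  }
};

// external toy potential (double well on the x coordinate of bead 0 with a
// harmonic restraint on y, z) so 1D analytic references can be simulated
struct ExtPot {
  int type;  // 0 none, 1 double well
  double barrier, x0, tilt, krest;
  double energy_forces(const std::vector<Vec3>& pos, std::vector<Vec3>& frc) const {
    if (type == 0) return 0.0;
    double x = pos[0].x, y = pos[0].y, z = pos[0].z;
    double u = (x / x0) * (x / x0) - 1.0;
    double v = barrier * u * u + tilt * x + 0.5 * krest * (y * y + z * z);
    frc[0].x -= barrier * 2.0 * u * 2.0 * x / (x0 * x0) + tilt;
    frc[0].y -= krest * y;
    frc[0].z -= krest * z;
    return v;
  }
};

// [[Rcpp::export]]
List run_cg_cpp(NumericMatrix pos0, List topo, List elec, List cfg) {
  Topology T = parse_topology(topo);
  ElecParams E = parse_elec(elec);

  double dt = as<double>(cfg["timestep"]);
  double gamma = as<double>(cfg["friction"]);
  double temp = as<double>(cfg["temperature"]);
  long nsteps = (long)as<double>(cfg["n_steps"]);
  unsigned long seed = (unsigned long)as<double>(cfg["seed"]);
  int stride = as<int>(cfg["record_stride"]);
  bool rec_frames = as<bool>(cfg["record_frames"]);
  double conf_r = as<double>(cfg["confine_radius"]);
  double conf_k = as<double>(cfg["confine_k"]);
  NumericVector cc = cfg["confine_center"];
  bool stop_bound = as<bool>(cfg["stop_when_bound"]);
  double bound_q = as<double>(cfg["bound_threshold"]);
  double q_lambda = as<double>(cfg["q_lambda"]);

  BiasState B;
  B.type = as<int>(cfg["bias_type"]);
  B.cv_type = as<int>(cfg["cv_type"]);
  B.cv_bead = as<int>(cfg["cv_bead"]) - 1;
  B.cv_k = as<double>(cfg["cv_steepness"]);
  B.cv_lambda = as<double>(cfg["cv_lambda"]);
  B.umb_k = as<double>(cfg["umbrella_k"]);
  B.umb_c = as<double>(cfg["umbrella_center"]);
  B.wtm_h0 = as<double>(cfg["wtm_height"]);
  B.wtm_sigma = as<double>(cfg["wtm_width"]);
  B.wtm_bf = as<double>(cfg["wtm_bias_factor"]);
  B.wtm_stride = as<int>(cfg["wtm_stride"]);
  B.kT = temp;
  if (B.type == 2)
    B.init_grid(as<double>(cfg["wtm_grid_min"]),
                as<double>(cfg["wtm_grid_max"]),
                as<int>(cfg["wtm_grid_n"]));

  ExtPot X;
  X.type = as<int>(cfg["ext_type"]);
  X.barrier = as<double>(cfg["ext_barrier"]);
  X.x0 = as<double>(cfg["ext_x0"]);
  X.tilt = as<double>(cfg["ext_tilt"]);
  X.krest = as<double>(cfg["ext_krest"]);

  int n = T.n;
  std::vector<Vec3> x(n), v(n), f(n), qgrad(n);
  for (int i = 0; i < n; ++i) x[i] = {pos0(i, 0), pos0(i, 1), pos0(i, 2)};

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double sd_v = std::sqrt(temp);
  bool has_v0 = cfg.containsElementNamed("vel0") && !Rf_isNull(cfg["vel0"]);
  if (has_v0) {
    NumericMatrix v0 = cfg["vel0"];
    for (int i = 0; i < n; ++i) v[i] = {v0(i, 0), v0(i, 1), v0(i, 2)};
  } else {
    for (int i = 0; i < n; ++i)
      v[i] = {sd_v * gauss(rng), sd_v * gauss(rng), sd_v * gauss(rng)};
  }

  double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  double c2 = (gamma > 0) ? std::sqrt((1.0 - c1 * c1) * temp) : 0.0;

  long nrec = nsteps / stride + 1;
  int NOBS = 16;
  NumericMatrix obs(nrec, NOBS);
  NumericVector frames;
  if (rec_frames) {
    frames = NumericVector(Dimension(n, 3, nrec));
  }

  double eterm[E_NTERMS];
  auto eval_forces = [&](double& epot, double& ebias, double& eext, double& cv) {
    compute_forces(x, T, E, eterm, f);
    eext = X.energy_forces(x, f);
    epot = eext;
    for (int t = 0; t < E_NTERMS; ++t) epot += eterm[t];
    // confinement
    if (conf_r > 0) {
      for (int i = 0; i < n; ++i) {
        double dx = x[i].x - cc[0], dy = x[i].y - cc[1], dz = x[i].z - cc[2];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (d > conf_r) {
          double ex = d - conf_r;
          epot += 0.5 * conf_k * ex * ex;
          double fw = -conf_k * ex / d;
          f[i].x += fw * dx; f[i].y += fw * dy; f[i].z += fw * dz;
        }
      }
    }
    // bias
    cv = NA_REAL;
    ebias = 0.0;
    if (B.type > 0) {
      if (B.cv_type == 0) {
        cv = smooth_q_internal(x, T, true, B.cv_k, B.cv_lambda, &qgrad);
      } else {
        cv = x[B.cv_bead].x;
      }
      ebias = B.bias_value(cv);
      double dv = B.bias_deriv(cv);
      if (B.cv_type == 0) {
        for (int i = 0; i < n; ++i) {
          f[i].x -= dv * qgrad[i].x;
          f[i].y -= dv * qgrad[i].y;
          f[i].z -= dv * qgrad[i].z;
        }
      } else {
        f[B.cv_bead].x -= dv;
      }
    }
  };

  double epot, ebias, eext, cv;
  eval_forces(epot, ebias, eext, cv);

  int irec = 0;
  bool stopped = false;
  long step_stop = -1;
  auto record = [&](long step) {
    double ekin = 0.0;
    for (int i = 0; i < n; ++i) ekin += 0.5 * dot(v[i], v[i]);
    double qi = hard_q(x, T, true, q_lambda);
    double qa = hard_q(x, T, false, q_lambda);
    obs(irec, 0) = step;
    obs(irec, 1) = step * dt;
    obs(irec, 2) = eterm[E_BOND];
    obs(irec, 3) = eterm[E_ANGLE];
    obs(irec, 4) = eterm[E_DIH];
    obs(irec, 5) = eterm[E_CONTACT];
    obs(irec, 6) = eterm[E_EV];
    obs(irec, 7) = eterm[E_ELEC];
    obs(irec, 8) = epot;
    obs(irec, 9) = ekin;
    obs(irec, 10) = ebias;
    obs(irec, 11) = cv;
    obs(irec, 12) = qi;
    obs(irec, 13) = qa;
    obs(irec, 14) = min_inter_dist(x, T);
    obs(irec, 15) = ligand_rg(x, T);
    if (rec_frames) {
      for (int i = 0; i < n; ++i) {
        frames[i + (long)n * 0 + (long)3 * n * irec] = x[i].x;
        frames[i + (long)n * 1 + (long)3 * n * irec] = x[i].y;
        frames[i + (long)n * 2 + (long)3 * n * irec] = x[i].z;
      }
    }
    ++irec;
  };
  record(0);

  for (long step = 1; step <= nsteps; ++step) {
    // BAOAB
    for (int i = 0; i < n; ++i) {
      v[i].x += 0.5 * dt * f[i].x;
      v[i].y += 0.5 * dt * f[i].y;
      v[i].z += 0.5 * dt * f[i].z;
      x[i].x += 0.5 * dt * v[i].x;
      x[i].y += 0.5 * dt * v[i].y;
      x[i].z += 0.5 * dt * v[i].z;
    }
    if (gamma > 0) {
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * gauss(rng);
        v[i].y = c1 * v[i].y + c2 * gauss(rng);
        v[i].z = c1 * v[i].z + c2 * gauss(rng);
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i].x += 0.5 * dt * v[i].x;
      x[i].y += 0.5 * dt * v[i].y;
      x[i].z += 0.5 * dt * v[i].z;
    }
    eval_forces(epot, ebias, eext, cv);
    for (int i = 0; i < n; ++i) {
      v[i].x += 0.5 * dt * f[i].x;
      v[i].y += 0.5 * dt * f[i].y;
      v[i].z += 0.5 * dt * f[i].z;
    }

    if (!std::isfinite(epot) || std::fabs(epot) > 1e6)
      stop("energy divergence at step %ld (V = %g); reduce the timestep", step, epot);

    // WTM deposition
    if (B.type == 2 && step % B.wtm_stride == 0) {
      double vb = B.bias_value(cv);
      double dT = (B.wtm_bf - 1.0) * B.kT;
      double h = B.wtm_h0 * std::exp(-vb / dT);
      B.centers.push_back(cv);
      B.heights.push_back(h);
      B.times.push_back(step * dt);
      B.deposit(cv, h);
      // re-evaluate bias force with the new Gaussian included
      eval_forces(epot, ebias, eext, cv);
    }

    if (step % stride == 0) {
      record(step);
      // binding commit is assessed at record resolution
      if (stop_bound && obs(irec - 1, 12) >= bound_q) {
        stopped = true;
        step_stop = step;
        break;
      }
    }
  }

  // trim records
  NumericMatrix obs_out(irec, NOBS);
  for (int r = 0; r < irec; ++r)
    for (int cidx = 0; cidx < NOBS; ++cidx) obs_out(r, cidx) = obs(r, cidx);
  colnames(obs_out) = CharacterVector::create(
      "step", "time", "e_bond", "e_angle", "e_dihedral", "e_contact",
      "e_excluded_volume", "e_electrostatic", "e_potential", "e_kinetic",
      "e_bias", "cv", "q_inter", "q_intra", "min_inter_dist", "rg_ligand");

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i) {
    xf(i, 0) = x[i].x; xf(i, 1) = x[i].y; xf(i, 2) = x[i].z;
    vf(i, 0) = v[i].x; vf(i, 1) = v[i].y; vf(i, 2) = v[i].z;
  }

  RObject ledger = R_NilValue;
  if (B.type == 2) {
    int ng = B.centers.size();
    NumericMatrix lg(ng, 3);
    for (int g = 0; g < ng; ++g) {
      lg(g, 0) = B.times[g]; lg(g, 1) = B.centers[g]; lg(g, 2) = B.heights[g];
    }
    colnames(lg) = CharacterVector::create("time", "center", "height");
    ledger = (SEXP)lg;
  }

  List out = List::create(
      _["obs"] = obs_out, _["final_pos"] = xf, _["final_vel"] = vf,
      _["stopped_early"] = stopped, _["stop_step"] = (double)step_stop,
      _["ledger"] = ledger);
  if (rec_frames) {
    out["frames"] = frames;
  }
  return out;
}
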