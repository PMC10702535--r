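// Metropolis Monte Carlo engine for rigid coarse-grained molecules with
// a WCA + shifted-SASA pair potential.  Canonical and grand-canonical
// ensembles; single-molecule, cluster and insertion/deletion moves;
// Widom insertions, virtual-volume pressure samples, COM-COM RDF and
// density/energy traces.
//
// Units: Angstrom, kJ/mol.  beta is in mol/kJ.  Molecule-based minimum
// image: the COM displacement is min-imaged once and applied to all bead
// pairs, valid because the interaction cutoff is far below L/2.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <algorithm>
#include <array>

using namespace Rcpp;

namespace {

struct Model {
  int nb;
  std::vector<double> body;        // 3*nb body-frame bead coords
  std::vector<double> sigma, eps, pref, contact, rc2wca; // nb*nb
  std::vector<double> R;           // nb SASA radii
  double rcut2;                    // molecule COM cutoff squared
};

struct System {
  std::vector<double> com;   // 3*N (wrapped into [0,L))
  std::vector<double> rot;   // 9*N row-major rotation matrices
  std::vector<double> brel;  // 3*nb*N bead coords relative to COM
  int N = 0;
};

inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  return x >= L ? x - L : x;
}

inline double minimg(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

// buried-area change of a bead pair relative to non-overlap (<= 0)
inline double lens_dA(double Ri, double Rj, double d) {
  double Rb = Ri > Rj ? Ri : Rj, rs = Ri > Rj ? Rj : Ri;
  if (d >= Rb + rs) return 0.0;
  if (d <= Rb - rs) return -4.0 * M_PI * rs * rs;
  double h1 = (Rj - Ri + d) * (Rj + Ri - d) / (2.0 * d); // cap on i
  double h2 = (Ri - Rj + d) * (Ri + Rj - d) / (2.0 * d); // cap on j
  return -2.0 * M_PI * (Ri * h1 + Rj * h2);
}

// interaction energy of one bead pair at squared distance r2
inline double pair_bead_energy(const Model& m, int a, int b, double r2) {
  int k = a * m.nb + b;
  double u = 0.0;
  if (r2 < m.rc2wca[k]) {
    if (r2 <= 0.0) return R_PosInf;
    double s2 = m.sigma[k] * m.sigma[k] / r2;
    double s6 = s2 * s2 * s2;
    u += 4.0 * m.eps[k] * (s6 * s6 - s6) + m.eps[k];
  }
  double c = m.contact[k];
  if (m.pref[k] != 0.0 && r2 < c * c)
    u += m.pref[k] * lens_dA(m.R[a], m.R[b], std::sqrt(r2));
  return u;
}

// molecule-molecule energy given the min-imaged COM displacement d[3]
double mol_pair_energy(const Model& m, const double* bi, const double* bj,
                       const double* d) {
  double u = 0.0;
  for (int a = 0; a < m.nb; ++a) {
    for (int b = 0; b < m.nb; ++b) {
      double dx = bj[3 * b]     + d[0] - bi[3 * a];
      double dy = bj[3 * b + 1] + d[1] - bi[3 * a + 1];
      double dz = bj[3 * b + 2] + d[2] - bi[3 * a + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double ub = pair_bead_energy(m, a, b, r2);
      if (ub == R_PosInf) return R_PosInf;
      u += ub;
    }
  }
  return u;
}

// energy of molecule i against all others (or a trial molecule)
double one_mol_energy(const Model& m, const System& s, double L,
                      const double* ci, const double* bi, int skip) {
  double u = 0.0;
  for (int j = 0; j < s.N; ++j) {
    if (j == skip) continue;
    double d[3];
    d[0] = minimg(s.com[3 * j]     - ci[0], L);
    d[1] = minimg(s.com[3 * j + 1] - ci[1], L);
    d[2] = minimg(s.com[3 * j + 2] - ci[2], L);
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 > m.rcut2) continue;
    double up = mol_pair_energy(m, bi, &s.brel[3 * m.nb * j], d);
    if (up == R_PosInf) return R_PosInf;
    u += up;
  }
  return u;
}

double total_energy(const Model& m, const System& s, double L) {
  double u = 0.0;
  for (int i = 0; i < s.N; ++i) {
    for (int j = i + 1; j < s.N; ++j) {
      double d[3];
      d[0] = minimg(s.com[3 * j]     - s.com[3 * i], L);
      d[1] = minimg(s.com[3 * j + 1] - s.com[3 * i + 1], L);
      d[2] = minimg(s.com[3 * j + 2] - s.com[3 * i + 2], L);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > m.rcut2) continue;
      double up = mol_pair_energy(m, &s.brel[3 * m.nb * i],
                                  &s.brel[3 * m.nb * j], d);
      if (up == R_PosInf) return R_PosInf;
      u += up;
    }
  }
  return u;
}

// total energy with COMs isotropically rescaled by factor f (box L*f)
double total_energy_scaled(const Model& m, const System& s, double L,
                           double f) {
  double Ls = L * f;
  double u = 0.0;
  for (int i = 0; i < s.N; ++i) {
    for (int j = i + 1; j < s.N; ++j) {
      double d[3];
      d[0] = minimg(f * (s.com[3 * j]     - s.com[3 * i]), Ls);
      d[1] = minimg(f * (s.com[3 * j + 1] - s.com[3 * i + 1]), Ls);
      d[2] = minimg(f * (s.com[3 * j + 2] - s.com[3 * i + 2]), Ls);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > m.rcut2) continue;
      double up = mol_pair_energy(m, &s.brel[3 * m.nb * i],
                                  &s.brel[3 * m.nb * j], d);
      if (up == R_PosInf) return R_PosInf;
      u += up;
    }
  }
  return u;
}

void rebuild_brel(const Model& m, System& s, int i) {
  const double* Rm = &s.rot[9 * i];
  for (int b = 0; b < m.nb; ++b) {
    const double* p = &m.body[3 * b];
    double* o = &s.brel[3 * m.nb * i + 3 * b];
    o[0] = Rm[0] * p[0] + Rm[1] * p[1] + Rm[2] * p[2];
    o[1] = Rm[3] * p[0] + Rm[4] * p[1] + Rm[5] * p[2];
    o[2] = Rm[6] * p[0] + Rm[7] * p[1] + Rm[8] * p[2];
  }
}

void mat_mul(const double* A, const double* B, double* C) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      C[3 * i + j] = A[3 * i] * B[j] + A[3 * i + 1] * B[3 + j] +
                     A[3 * i + 2] * B[6 + j];
}

struct Rng {
  std::mt19937_64 gen;
  std::uniform_real_distribution<double> u01{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
  explicit Rng(uint64_t seed) : gen(seed) {}
  double unif() { return u01(gen); }
  double unif(double a, double b) { return a + (b - a) * u01(gen); }
  int unif_int(int n) { return std::min<int>(n - 1, int(u01(gen) * n)); }
  // axis uniform on the sphere
  void axis(double* a) {
    double n2;
    do {
      a[0] = norm(gen); a[1] = norm(gen); a[2] = norm(gen);
      n2 = a[0] * a[0] + a[1] * a[1] + a[2] * a[2];
    } while (n2 < 1e-12);
    double n = std::sqrt(n2);
    a[0] /= n; a[1] /= n; a[2] /= n;
  }
  void rot_matrix(double maxang, double* Rm) {
    double a[3];
    axis(a);
    double t = unif(-maxang, maxang);
    double c = std::cos(t), s = std::sin(t), C = 1 - c;
    Rm[0] = c + a[0] * a[0] * C;      Rm[1] = a[0] * a[1] * C - a[2] * s;
    Rm[2] = a[0] * a[2] * C + a[1] * s;
    Rm[3] = a[1] * a[0] * C + a[2] * s; Rm[4] = c + a[1] * a[1] * C;
    Rm[5] = a[1] * a[2] * C - a[0] * s;
    Rm[6] = a[2] * a[0] * C - a[1] * s; Rm[7] = a[2] * a[1] * C + a[0] * s;
    Rm[8] = c + a[2] * a[2] * C;
  }
  // uniform random rotation from a random unit quaternion
  void random_rot(double* Rm) {
    double q[4], n2 = 0;
    for (int k = 0; k < 4; ++k) { q[k] = norm(gen); n2 += q[k] * q[k]; }
    double n = std::sqrt(n2);
    for (int k = 0; k < 4; ++k) q[k] /= n;
    double w = q[0], x = q[1], y = q[2], z = q[3];
    Rm[0] = 1 - 2 * (y * y + z * z); Rm[1] = 2 * (x * y - w * z);
    Rm[2] = 2 * (x * z + w * y);
    Rm[3] = 2 * (x * y + w * z); Rm[4] = 1 - 2 * (x * x + z * z);
    Rm[5] = 2 * (y * z - w * x);
    Rm[6] = 2 * (x * z - w * y); Rm[7] = 2 * (y * z + w * x);
    Rm[8] = 1 - 2 * (x * x + y * y);
  }
};

Model unpack_model(const List& tpl) {
  Model m;
  NumericMatrix body = tpl["body"];      // 3 x nb
  m.nb = body.ncol();
  m.body.assign(body.begin(), body.end());
  NumericMatrix sg = tpl["sigma"], ep = tpl["eps"], pf = tpl["pref"],
                ct = tpl["contact"];
  m.sigma.assign(sg.begin(), sg.end());
  m.eps.assign(ep.begin(), ep.end());
  m.pref.assign(pf.begin(), pf.end());
  m.contact.assign(ct.begin(), ct.end());
  m.rc2wca.resize(m.sigma.size());
  double maxreach = 0.0, molrad = 0.0;
  for (size_t k = 0; k < m.sigma.size(); ++k) {
    double rc = std::pow(2.0, 1.0 / 6.0) * m.sigma[k];
    m.rc2wca[k] = rc * rc;
    maxreach = std::max(maxreach, std::max(rc, m.contact[k]));
  }
  m.R.resize(m.nb);
  for (int b = 0; b < m.nb; ++b) {
    // per-bead SASA radius from the diagonal of the contact matrix
    m.R[b] = m.contact[b * m.nb + b] / 2.0;
    double d2 = m.body[3 * b] * m.body[3 * b] +
                m.body[3 * b + 1] * m.body[3 * b + 1] +
                m.body[3 * b + 2] * m.body[3 * b + 2];
    molrad = std::max(molrad, std::sqrt(d2));
  }
  double rcut = maxreach + 2.0 * molrad;
  m.rcut2 = rcut * rcut;
  return m;
}

System unpack_system(const Model& m, const NumericMatrix& com,
                     const NumericMatrix& rot, double L) {
  System s;
  s.N = com.ncol();
  s.com.assign(com.begin(), com.end());
  for (int i = 0; i < 3 * s.N; ++i) s.com[i] = wrap1(s.com[i], L);
  s.rot.assign(rot.begin(), rot.end());
  s.brel.resize(size_t(3) * m.nb * s.N);
  for (int i = 0; i < s.N; ++i) rebuild_brel(m, s, i);
  return s;
}

} // namespace

// [[Rcpp::export]]
double total_energy_cpp(List tpl, NumericMatrix com, NumericMatrix rot9,
                        double box) {
  Model m = unpack_model(tpl);
  if (std::sqrt(m.rcut2) >= box / 2.0)
    stop("interaction cutoff exceeds half the box length");
  System s = unpack_system(m, com, rot9, box);
  return total_energy(m, s, box);
}

// [[Rcpp::export]]
List run_mc_cpp(List tpl, NumericMatrix com0, NumericMatrix rot0,
                double box, double beta, double u1, bool grand,
                double a_num, List moves, List protocol) {
  Model m = unpack_model(tpl);
  if (std::sqrt(m.rcut2) >= box / 2.0)
    stop("interaction cutoff exceeds half the box length");
  System s = unpack_system(m, com0, rot0, box);
  double L = box, V = L * L * L;

  double dtrans = moves["dtrans"], drot = moves["drot"];
  double cl_dtrans = moves["cl_dtrans"], cl_drot = moves["cl_drot"];
  double cl_thresh = moves["cl_threshold"];
  double w_trans = moves["w_trans"], w_cluster = moves["w_cluster"],
         w_gc = grand ? double(moves["w_gc"]) : 0.0;
  double wsum = w_trans + w_cluster + w_gc;
  if (wsum <= 0) stop("no moves enabled");

  double n_equil = protocol["equilibration"], n_prod = protocol["production"];
  int rdf_stride = protocol["rdf_stride"];
  double rdf_dr = protocol["rdf_dr"];
  int widom_stride = protocol["widom_stride"];
  int widom_inserts = protocol["widom_inserts"];
  int pressure_stride = protocol["pressure_stride"];
  double dV = protocol["dV"];
  int density_stride = protocol["density_stride"];
  int energy_stride = protocol["energy_stride"];
  uint64_t seed = (uint64_t)(double)protocol["seed"];
  Rng rng(seed);

  if (dV >= V) stop("volume perturbation must be smaller than the box volume");

  int nbins = rdf_stride > 0 ? int(std::floor((L / 2.0) / rdf_dr)) : 0;
  std::vector<double> rdf_counts(nbins, 0.0);
  double rdf_norm = 0.0;
  long rdf_frames = 0;
  std::vector<double> widom_samples, press_samples, energy_trace;
  std::vector<double> density_trace;
  double press_N_sum = 0.0;
  long press_n = 0;

  double U = total_energy(m, s, L);
  if (U == R_PosInf && n_equil + n_prod > 0) {
    // relax hard overlaps of a random initial configuration: treated as a
    // very large but finite energy so that downhill moves are accepted
    U = 1e12;
  }
  double dU_accum = 0.0;
  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0}; // trans, cluster, ins, del

  std::vector<int> cl_idx, cl_idx2;
  std::vector<char> in_cl;
  std::vector<double> unwrapped;

  auto metropolis = [&](double du, double logbias) -> bool {
    if (ISNAN(du)) stop("NaN energy change in MC move");
    if (du == R_PosInf) return false;
    double x = -beta * du + logbias;
    if (x >= 0) return true;
    return rng.unif() < std::exp(x);
  };

  // transitive closure of COM distance <= threshold from seed molecule;
  // fills cl_idx (members) and unwrapped coordinates relative to seed
  auto build_cluster = [&](int seedmol, std::vector<int>& idx,
                           std::vector<double>* unwr) {
    idx.clear();
    in_cl.assign(s.N, 0);
    std::vector<int> queue{seedmol};
    in_cl[seedmol] = 1;
    std::vector<double> upos(3 * s.N, 0.0);
    upos[0] = s.com[3 * seedmol];
    upos[1] = s.com[3 * seedmol + 1];
    upos[2] = s.com[3 * seedmol + 2];
    // store per-molecule unwrapped coords keyed by position in idx
    std::vector<std::array<double, 3>> uw;
    std::array<double, 3> u0{{s.com[3 * seedmol], s.com[3 * seedmol + 1],
                              s.com[3 * seedmol + 2]}};
    idx.push_back(seedmol);
    uw.push_back(u0);
    size_t head = 0;
    double th2 = cl_thresh * cl_thresh;
    while (head < idx.size()) {
      int i = idx[head];
      std::array<double, 3> ui = uw[head];
      ++head;
      for (int j = 0; j < s.N; ++j) {
        if (in_cl[j]) continue;
        double d[3];
        d[0] = minimg(s.com[3 * j]     - s.com[3 * i], L);
        d[1] = minimg(s.com[3 * j + 1] - s.com[3 * i + 1], L);
        d[2] = minimg(s.com[3 * j + 2] - s.com[3 * i + 2], L);
        if (d[0] * d[0] + d[1] * d[1] + d[2] * d[2] <= th2) {
          in_cl[j] = 1;
          idx.push_back(j);
          uw.push_back({{ui[0] + d[0], ui[1] + d[1], ui[2] + d[2]}});
        }
      }
    }
    if (unwr) {
      unwr->resize(3 * idx.size());
      for (size_t k = 0; k < idx.size(); ++k) {
        (*unwr)[3 * k] = uw[k][0];
        (*unwr)[3 * k + 1] = uw[k][1];
        (*unwr)[3 * k + 2] = uw[k][2];
      }
    }
  };

  // external energy of the cluster (members vs non-members)
  auto cluster_external = [&](const std::vector<int>& idx) -> double {
    double u = 0.0;
    for (int i : idx) {
      for (int j = 0; j < s.N; ++j) {
        if (in_cl[j]) continue;
        double d[3];
        d[0] = minimg(s.com[3 * j]     - s.com[3 * i], L);
        d[1] = minimg(s.com[3 * j + 1] - s.com[3 * i + 1], L);
        d[2] = minimg(s.com[3 * j + 2] - s.com[3 * i + 2], L);
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 > m.rcut2) continue;
        double up = mol_pair_energy(m, &s.brel[3 * m.nb * i],
                                    &s.brel[3 * m.nb * j], d);
        if (up == R_PosInf) return R_PosInf;
        u += up;
      }
    }
    return u;
  };

  auto do_move = [&]() {
    double pick = rng.unif() * wsum;
    if (pick < w_trans) {
      // single-molecule translation + rotation
      ++att[0];
      if (s.N == 0) return;
      int i = rng.unif_int(s.N);
      double oldc[3] = {s.com[3 * i], s.com[3 * i + 1], s.com[3 * i + 2]};
      std::vector<double> oldb(&s.brel[3 * m.nb * i],
                               &s.brel[3 * m.nb * i] + 3 * m.nb);
      double oldr[9];
      std::copy(&s.rot[9 * i], &s.rot[9 * i] + 9, oldr);
      double u_old = one_mol_energy(m, s, L, oldc, oldb.data(), i);
      double dir[3];
      rng.axis(dir);
      double step = rng.unif() * dtrans;
      double newc[3] = {wrap1(oldc[0] + step * dir[0], L),
                        wrap1(oldc[1] + step * dir[1], L),
                        wrap1(oldc[2] + step * dir[2], L)};
      double dR[9], newr[9];
      rng.rot_matrix(drot, dR);
      mat_mul(dR, oldr, newr);
      std::copy(newr, newr + 9, &s.rot[9 * i]);
      std::copy(newc, newc + 3, &s.com[3 * i]);
      rebuild_brel(m, s, i);
      double u_new = one_mol_energy(m, s, L, &s.com[3 * i],
                                    &s.brel[3 * m.nb * i], i);
      double du = u_new - u_old;
      if (u_old == R_PosInf && u_new < R_PosInf) du = -1e12; // escape overlap
      if (metropolis(du, 0.0)) {
        ++acc[0];
        U += du;
        dU_accum += du;
      } else {
        std::copy(oldc, oldc + 3, &s.com[3 * i]);
        std::copy(oldr, oldr + 9, &s.rot[9 * i]);
        std::copy(oldb.begin(), oldb.end(), &s.brel[3 * m.nb * i]);
      }
    } else if (pick < w_trans + w_cluster) {
      // rigid cluster translation + rotation with membership guard
      ++att[1];
      if (s.N == 0) return;
      int seedmol = rng.unif_int(s.N);
      build_cluster(seedmol, cl_idx, &unwrapped);
      double u_old = cluster_external(cl_idx);
      // backup
      std::vector<double> bak_com, bak_rot, bak_brel;
      bak_com.reserve(3 * cl_idx.size());
      bak_rot.reserve(9 * cl_idx.size());
      bak_brel.reserve(3 * m.nb * cl_idx.size());
      for (int i : cl_idx) {
        bak_com.insert(bak_com.end(), &s.com[3 * i], &s.com[3 * i] + 3);
        bak_rot.insert(bak_rot.end(), &s.rot[9 * i], &s.rot[9 * i] + 9);
        bak_brel.insert(bak_brel.end(), &s.brel[3 * m.nb * i],
                        &s.brel[3 * m.nb * i] + 3 * m.nb);
      }
      // centroid of unwrapped cluster coordinates
      double cen[3] = {0, 0, 0};
      for (size_t k = 0; k < cl_idx.size(); ++k)
        for (int c = 0; c < 3; ++c) cen[c] += unwrapped[3 * k + c];
      for (int c = 0; c < 3; ++c) cen[c] /= cl_idx.size();
      double dir[3];
      rng.axis(dir);
      double step = rng.unif() * cl_dtrans;
      double dR[9];
      rng.rot_matrix(cl_drot, dR);
      for (size_t k = 0; k < cl_idx.size(); ++k) {
        int i = cl_idx[k];
        double v[3] = {unwrapped[3 * k] - cen[0],
                       unwrapped[3 * k + 1] - cen[1],
                       unwrapped[3 * k + 2] - cen[2]};
        double w[3] = {dR[0] * v[0] + dR[1] * v[1] + dR[2] * v[2],
                       dR[3] * v[0] + dR[4] * v[1] + dR[5] * v[2],
                       dR[6] * v[0] + dR[7] * v[1] + dR[8] * v[2]};
        for (int c = 0; c < 3; ++c)
          s.com[3 * i + c] = wrap1(cen[c] + w[c] + step * dir[c], L);
        double newr[9];
        mat_mul(dR, &s.rot[9 * i], newr);
        std::copy(newr, newr + 9, &s.rot[9 * i]);
        rebuild_brel(m, s, i);
      }
      bool ok = true;
      // membership guard: cluster recomputed from the same seed must match
      build_cluster(seedmol, cl_idx2, nullptr);
      if (cl_idx2.size() != cl_idx.size()) ok = false;
      if (ok) {
        std::vector<int> a = cl_idx, b = cl_idx2;
        std::sort(a.begin(), a.end());
        std::sort(b.begin(), b.end());
        ok = (a == b);
      }
      double du = 0.0;
      if (ok) {
        // restore membership flags for the external-energy evaluation
        in_cl.assign(s.N, 0);
        for (int i : cl_idx) in_cl[i] = 1;
        double u_new = cluster_external(cl_idx);
        du = u_new - u_old;
        if (u_old == R_PosInf && u_new < R_PosInf) du = -1e12;
        ok = metropolis(du, 0.0);
      }
      if (ok) {
        ++acc[1];
        U += du;
        dU_accum += du;
      } else {
        for (size_t k = 0; k < cl_idx.size(); ++k) {
          int i = cl_idx[k];
          std::copy(&bak_com[3 * k], &bak_com[3 * k] + 3, &s.com[3 * i]);
          std::copy(&bak_rot[9 * k], &bak_rot[9 * k] + 9, &s.rot[9 * i]);
          std::copy(&bak_brel[3 * m.nb * k],
                    &bak_brel[3 * m.nb * k] + 3 * m.nb,
                    &s.brel[3 * m.nb * i]);
        }
      }
    } else {
      // grand-canonical insertion / deletion
      bool insert = rng.unif() < 0.5;
      if (insert) {
        ++att[2];
        double c[3] = {rng.unif() * L, rng.unif() * L, rng.unif() * L};
        double Rm9[9];
        rng.random_rot(Rm9);
        std::vector<double> b(3 * m.nb);
        for (int bd = 0; bd < m.nb; ++bd) {
          const double* p = &m.body[3 * bd];
          b[3 * bd]     = Rm9[0] * p[0] + Rm9[1] * p[1] + Rm9[2] * p[2];
          b[3 * bd + 1] = Rm9[3] * p[0] + Rm9[4] * p[1] + Rm9[5] * p[2];
          b[3 * bd + 2] = Rm9[6] * p[0] + Rm9[7] * p[1] + Rm9[8] * p[2];
        }
        double du = one_mol_energy(m, s, L, c, b.data(), -1);
        if (du < R_PosInf) du += u1;
        double logbias = std::log(a_num * V / (s.N + 1));
        if (metropolis(du, logbias)) {
          ++acc[2];
          s.com.insert(s.com.end(), c, c + 3);
          s.rot.insert(s.rot.end(), Rm9, Rm9 + 9);
          s.brel.insert(s.brel.end(), b.begin(), b.end());
          ++s.N;
          U += du - u1;
          dU_accum += du - u1;
        }
      } else {
        ++att[3];
        if (s.N == 0) return;
        int i = rng.unif_int(s.N);
        double ui = one_mol_energy(m, s, L, &s.com[3 * i],
                                   &s.brel[3 * m.nb * i], i);
        double du = (ui == R_PosInf) ? R_NegInf : -(ui + u1);
        double logbias = std::log(s.N / (a_num * V));
        bool accept;
        if (du == R_NegInf) accept = true;
        else accept = metropolis(du, logbias);
        if (accept) {
          ++acc[3];
          int last = s.N - 1;
          if (i != last) {
            std::copy(&s.com[3 * last], &s.com[3 * last] + 3, &s.com[3 * i]);
            std::copy(&s.rot[9 * last], &s.rot[9 * last] + 9, &s.rot[9 * i]);
            std::copy(&s.brel[3 * m.nb * last],
                      &s.brel[3 * m.nb * last] + 3 * m.nb,
                      &s.brel[3 * m.nb * i]);
          }
          s.com.resize(3 * last);
          s.rot.resize(9 * last);
          s.brel.resize(size_t(3) * m.nb * last);
          s.N = last;
          double dui = (ui == R_PosInf) ? 0.0 : -ui;
          U += dui;
          dU_accum += dui;
        }
      }
    }
  };

  for (double it = 0; it < n_equil; ++it) do_move();

  long step = 0;
  for (double it = 0; it < n_prod; ++it) {
    do_move();
    ++step;
    if (rdf_stride > 0 && step % rdf_stride == 0) {
      for (int i = 0; i < s.N; ++i) {
        for (int j = i + 1; j < s.N; ++j) {
          double dx = minimg(s.com[3 * j] - s.com[3 * i], L);
          double dy = minimg(s.com[3 * j + 1] - s.com[3 * i + 1], L);
          double dz = minimg(s.com[3 * j + 2] - s.com[3 * i + 2], L);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          int b = int(r / rdf_dr);
          if (b < nbins) rdf_counts[b] += 1.0;
        }
      }
      rdf_norm += s.N * double(s.N - 1) / (2.0 * V);
      ++rdf_frames;
    }
    if (widom_stride > 0 && step % widom_stride == 0) {
      double wsumi = 0.0;
      for (int k = 0; k < widom_inserts; ++k) {
        double c[3] = {rng.unif() * L, rng.unif() * L, rng.unif() * L};
        double Rm9[9];
        rng.random_rot(Rm9);
        std::vector<double> b(3 * m.nb);
        for (int bd = 0; bd < m.nb; ++bd) {
          const double* p = &m.body[3 * bd];
          b[3 * bd]     = Rm9[0] * p[0] + Rm9[1] * p[1] + Rm9[2] * p[2];
          b[3 * bd + 1] = Rm9[3] * p[0] + Rm9[4] * p[1] + Rm9[5] * p[2];
          b[3 * bd + 2] = Rm9[6] * p[0] + Rm9[7] * p[1] + Rm9[8] * p[2];
        }
        double du = one_mol_energy(m, s, L, c, b.data(), -1);
        if (du < R_PosInf) wsumi += std::exp(-beta * (du + u1));
      }
      widom_samples.push_back(wsumi / widom_inserts);
    }
    if (pressure_stride > 0 && step % pressure_stride == 0) {
      double f = std::cbrt((V + dV) / V);
      double Us = total_energy_scaled(m, s, L, f);
      double x;
      if (Us == R_PosInf) x = R_NegInf;
      else x = s.N * std::log1p(dV / V) - beta * (Us - U);
      press_samples.push_back(x);
      press_N_sum += s.N;
      ++press_n;
    }
    if (density_stride > 0 && step % density_stride == 0)
      density_trace.push_back(double(s.N));
    if (energy_stride > 0 && step % energy_stride == 0)
      energy_trace.push_back(U);
  }

  double U_final = total_energy(m, s, L);

  NumericMatrix com_out(3, s.N), rot_out(9, s.N);
  std::copy(s.com.begin(), s.com.end(), com_out.begin());
  std::copy(s.rot.begin(), s.rot.end(), rot_out.begin());

  return List::create(
    _["com"] = com_out, _["rot"] = rot_out, _["n"] = s.N,
    _["energy"] = U_final, _["energy_incremental"] = U,
    _["du_accum"] = dU_accum,
    _["attempts"] = NumericVector::create(att[0], att[1], att[2], att[3]),
    _["accepts"] = NumericVector::create(acc[0], acc[1], acc[2], acc[3]),
    _["rdf_counts"] = wrap(rdf_counts), _["rdf_dr"] = rdf_dr,
    _["rdf_norm"] = rdf_norm, _["rdf_frames"] = double(rdf_frames),
    _["widom_samples"] = wrap(widom_samples),
    _["pressure_samples"] = wrap(press_samples),
    _["pressure_mean_n"] = press_n > 0 ? press_N_sum / press_n : NA_REAL,
    _["density_trace"] = wrap(density_trace),
    _["energy_trace"] = wrap(energy_trace));
}
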