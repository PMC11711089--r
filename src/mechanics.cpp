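// Finite-strain neo-Hookean + fiber FEM core on linear tetrahedra.
// Energy per tet: W = V_ref * det(Fg) * Psi(Fe), Fe = F * Fg^{-1},
// Psi = mu/2 (J^{-2/3} I1 - 3) + K/2 (J - 1)^2
//     + sum_i k_i/2 (I4_i - 1)^2 [tension only], I4_i = |Fe a_i|^2.
#include <RcppArmadillo.h>
#include <unordered_map>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_fem_precompute(const arma::mat& nodes, const arma::imat& tets) {
  const int m = tets.n_rows;
  arma::cube Bm(3, 3, m);
  arma::vec vol(m);
  for (int e = 0; e < m; ++e) {
    arma::mat Dm(3, 3);
    arma::rowvec p0 = nodes.row(tets(e, 0) - 1);
    for (int k = 0; k < 3; ++k)
      Dm.col(k) = (nodes.row(tets(e, k + 1) - 1) - p0).t();
    double det = arma::det(Dm);
    vol(e) = det / 6.0;
    if (vol(e) <= 0) stop("non-positive tet volume in precompute");
    Bm.slice(e) = arma::inv(Dm);
  }
  return List::create(_["Bm"] = Bm, _["vol"] = vol);
}

// Psi and P = dPsi/dFe for one element; returns false on inversion
static bool psi_and_stress(const arma::mat33& Fe, double mu, double K,
                           double k1, double k2, const arma::vec3& a1,
                           const arma::vec3& a2, bool has1, bool has2,
                           double& psi, arma::mat33& P) {
  double J = arma::det(Fe);
  if (J <= 0.0) return false;
  arma::mat33 FeiT = arma::inv(Fe).t();
  double I1 = arma::accu(Fe % Fe);
  double Jm23 = std::pow(J, -2.0 / 3.0);
  psi = 0.5 * mu * (Jm23 * I1 - 3.0) + 0.5 * K * (J - 1.0) * (J - 1.0);
  P = mu * Jm23 * (Fe - (I1 / 3.0) * FeiT) + K * (J - 1.0) * J * FeiT;
  if (has1 && k1 > 0) {
    arma::vec3 Fa = Fe * a1;
    double I4 = arma::dot(Fa, Fa);
    if (I4 > 1.0) {
      psi += 0.5 * k1 * (I4 - 1.0) * (I4 - 1.0);
      P += 2.0 * k1 * (I4 - 1.0) * (Fa * a1.t());
    }
  }
  if (has2 && k2 > 0) {
    arma::vec3 Fa = Fe * a2;
    double I4 = arma::dot(Fa, Fa);
    if (I4 > 1.0) {
      psi += 0.5 * k2 * (I4 - 1.0) * (I4 - 1.0);
      P += 2.0 * k2 * (I4 - 1.0) * (Fa * a2.t());
    }
  }
  return true;
}

// assemble total elastic energy and nodal forces (-gradient)
// mu,K,k1,k2: per-element; a1,a2: m x 3 (rows may be all-zero = absent);
// Fg: 3x3xm growth tensors. 3x3 algebra hand-coded: this kernel is the
// simulation hot spot on one CPU.
// [[Rcpp::export]]
List cpp_energy_forces(const arma::mat& x, const arma::imat& tets,
                       const arma::cube& Bm, const arma::vec& vol,
                       const arma::vec& mu, const arma::vec& K,
                       const arma::vec& k1, const arma::vec& k2,
                       const arma::mat& a1, const arma::mat& a2,
                       const arma::cube& Fg) {
  const int m = tets.n_rows, n = x.n_rows;
  arma::mat forces(n, 3, arma::fill::zeros);
  double E = 0.0, min_detFe = arma::datum::inf;
  int n_inverted = 0;
  const double* xp = x.memptr();          // column-major n x 3
  double* fp = forces.memptr();
  for (int e = 0; e < m; ++e) {
    const int i0 = tets(e, 0) - 1, i1 = tets(e, 1) - 1,
              i2 = tets(e, 2) - 1, i3 = tets(e, 3) - 1;
    // Ds columns = edge vectors (x_i - x_0)
    double D[9];
    for (int c = 0; c < 3; ++c) {
      const double x0 = xp[i0 + c * n];
      D[0 + c] = xp[i1 + c * n] - x0;     // row c of column 0 -> D[c][0]
      D[3 + c] = xp[i2 + c * n] - x0;
      D[6 + c] = xp[i3 + c * n] - x0;
    }
    // F = Ds * Bm (both 3x3, Bm column-major slice)
    const double* B = Bm.slice_memptr(e);
    double F[9];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        F[3 * c + r] = D[0 + r] * B[3 * c + 0] + D[3 + r] * B[3 * c + 1] +
                       D[6 + r] * B[3 * c + 2];
    // Fg inverse and determinant by cofactors
    const double* G = Fg.slice_memptr(e);
    const double detG =
      G[0] * (G[4] * G[8] - G[7] * G[5]) -
      G[3] * (G[1] * G[8] - G[7] * G[2]) +
      G[6] * (G[1] * G[5] - G[4] * G[2]);
    double Gi[9];
    {
      const double id = 1.0 / detG;
      Gi[0] = (G[4] * G[8] - G[7] * G[5]) * id;
      Gi[1] = -(G[1] * G[8] - G[7] * G[2]) * id;
      Gi[2] = (G[1] * G[5] - G[4] * G[2]) * id;
      Gi[3] = -(G[3] * G[8] - G[6] * G[5]) * id;
      Gi[4] = (G[0] * G[8] - G[6] * G[2]) * id;
      Gi[5] = -(G[0] * G[5] - G[3] * G[2]) * id;
      Gi[6] = (G[3] * G[7] - G[6] * G[4]) * id;
      Gi[7] = -(G[0] * G[7] - G[6] * G[1]) * id;
      Gi[8] = (G[0] * G[4] - G[3] * G[1]) * id;
    }
    // Fe = F * Gi
    double Fe[9];
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r)
        Fe[3 * c + r] = F[0 + r] * Gi[3 * c + 0] + F[3 + r] * Gi[3 * c + 1] +
                        F[6 + r] * Gi[3 * c + 2];
    const double J =
      Fe[0] * (Fe[4] * Fe[8] - Fe[7] * Fe[5]) -
      Fe[3] * (Fe[1] * Fe[8] - Fe[7] * Fe[2]) +
      Fe[6] * (Fe[1] * Fe[5] - Fe[4] * Fe[2]);
    if (J < min_detFe) min_detFe = J;
    const double w = vol(e) * detG;
    if (J <= 0.0) {
      ++n_inverted;
      E += 1e10 * w;  // inversion barrier keeps the guard honest
      continue;
    }
    // Fe^{-T} (transpose of cofactor inverse)
    double FiT[9];
    {
      const double id = 1.0 / J;
      const double c00 = (Fe[4] * Fe[8] - Fe[7] * Fe[5]) * id;
      const double c01 = -(Fe[1] * Fe[8] - Fe[7] * Fe[2]) * id;
      const double c02 = (Fe[1] * Fe[5] - Fe[4] * Fe[2]) * id;
      const double c10 = -(Fe[3] * Fe[8] - Fe[6] * Fe[5]) * id;
      const double c11 = (Fe[0] * Fe[8] - Fe[6] * Fe[2]) * id;
      const double c12 = -(Fe[0] * Fe[5] - Fe[3] * Fe[2]) * id;
      const double c20 = (Fe[3] * Fe[7] - Fe[6] * Fe[4]) * id;
      const double c21 = -(Fe[0] * Fe[7] - Fe[6] * Fe[1]) * id;
      const double c22 = (Fe[0] * Fe[4] - Fe[3] * Fe[1]) * id;
      // inv = [c00 c10 c20; c01 c11 c21; c02 c12 c22] (column-major),
      // so inv^T column-major = rows of inv
      FiT[0] = c00; FiT[1] = c10; FiT[2] = c20;
      FiT[3] = c01; FiT[4] = c11; FiT[5] = c21;
      FiT[6] = c02; FiT[7] = c12; FiT[8] = c22;
    }
    double I1 = 0.0;
    for (int q = 0; q < 9; ++q) I1 += Fe[q] * Fe[q];
    const double Jm23 = std::pow(J, -2.0 / 3.0);
    double psi = 0.5 * mu(e) * (Jm23 * I1 - 3.0) +
                 0.5 * K(e) * (J - 1.0) * (J - 1.0);
    double P[9];
    {
      const double cmu = mu(e) * Jm23, ck = K(e) * (J - 1.0) * J;
      const double ci = cmu * I1 / 3.0;
      for (int q = 0; q < 9; ++q) P[q] = cmu * Fe[q] - ci * FiT[q] + ck * FiT[q];
    }
    // tension-only fiber families
    for (int fam = 0; fam < 2; ++fam) {
      const double kf = fam == 0 ? k1(e) : k2(e);
      if (kf <= 0) continue;
      const arma::mat& A = fam == 0 ? a1 : a2;
      const double ax = A(e, 0), ay = A(e, 1), az = A(e, 2);
      if (ax * ax + ay * ay + az * az < 0.25) continue;
      const double Fa0 = Fe[0] * ax + Fe[3] * ay + Fe[6] * az;
      const double Fa1 = Fe[1] * ax + Fe[4] * ay + Fe[7] * az;
      const double Fa2 = Fe[2] * ax + Fe[5] * ay + Fe[8] * az;
      const double I4 = Fa0 * Fa0 + Fa1 * Fa1 + Fa2 * Fa2;
      if (I4 > 1.0) {
        psi += 0.5 * kf * (I4 - 1.0) * (I4 - 1.0);
        const double cf = 2.0 * kf * (I4 - 1.0);
        P[0] += cf * Fa0 * ax; P[1] += cf * Fa1 * ax; P[2] += cf * Fa2 * ax;
        P[3] += cf * Fa0 * ay; P[4] += cf * Fa1 * ay; P[5] += cf * Fa2 * ay;
        P[6] += cf * Fa0 * az; P[7] += cf * Fa1 * az; P[8] += cf * Fa2 * az;
      }
    }
    E += w * psi;
    // dE/dDs = w * (P * Gi^T) * Bm^T
    double PG[9];
    for (int c = 0; c < 3; ++c)       // column c of P * Gi^T
      for (int r = 0; r < 3; ++r)
        PG[3 * c + r] = P[0 + r] * Gi[0 + c] + P[3 + r] * Gi[3 + c] +
                        P[6 + r] * Gi[6 + c];
    double H[9];
    for (int c = 0; c < 3; ++c)       // column c of PG * Bm^T
      for (int r = 0; r < 3; ++r)
        H[3 * c + r] = w * (PG[0 + r] * B[0 + c] + PG[3 + r] * B[3 + c] +
                            PG[6 + r] * B[6 + c]);
    const int rows[3] = {i1, i2, i3};
    for (int c = 0; c < 3; ++c) {
      for (int k = 0; k < 3; ++k) {
        fp[rows[k] + c * n] -= H[3 * k + c];
        fp[i0 + c * n] += H[3 * k + c];
      }
    }
  }
  return List::create(_["energy"] = E, _["forces"] = forces,
                      _["min_detFe"] = min_detFe,
                      _["n_inverted"] = n_inverted);
}

struct SpatialHash {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> map;
  static int64_t key(int ix, int iy, int iz) {
    return (int64_t(ix) * 73856093LL) ^ (int64_t(iy) * 19349663LL) ^
           (int64_t(iz) * 83492791LL);
  }
  void insert_box(const arma::vec3& lo, const arma::vec3& hi, int id) {
    for (int ix = int(std::floor(lo(0) / cell)); ix <= int(std::floor(hi(0) / cell)); ++ix)
      for (int iy = int(std::floor(lo(1) / cell)); iy <= int(std::floor(hi(1) / cell)); ++iy)
        for (int iz = int(std::floor(lo(2) / cell)); iz <= int(std::floor(hi(2) / cell)); ++iz)
          map[key(ix, iy, iz)].push_back(id);
  }
  const std::vector<int>* query(const arma::vec3& p) const {
    auto it = map.find(key(int(std::floor(p(0) / cell)),
                           int(std::floor(p(1) / cell)),
                           int(std::floor(p(2) / cell))));
    return it == map.end() ? nullptr : &it->second;
  }
};

static arma::vec3 closest_on_triangle(const arma::vec3& p, const arma::vec3& A,
                                      const arma::vec3& B, const arma::vec3& C,
                                      double& w0, double& w1, double& w2) {
  // Ericson's closest-point-on-triangle
  arma::vec3 ab = B - A, ac = C - A, ap = p - A;
  double d1 = arma::dot(ab, ap), d2 = arma::dot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { w0 = 1; w1 = 0; w2 = 0; return A; }
  arma::vec3 bp = p - B;
  double d3 = arma::dot(ab, bp), d4 = arma::dot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { w0 = 0; w1 = 1; w2 = 0; return B; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    w0 = 1 - v; w1 = v; w2 = 0; return A + v * ab;
  }
  arma::vec3 cp = p - C;
  double d5 = arma::dot(ab, cp), d6 = arma::dot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { w0 = 0; w1 = 0; w2 = 1; return C; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    w0 = 1 - w; w1 = 0; w2 = w; return A + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    w0 = 0; w1 = 1 - w; w2 = w; return B + w * (C - B);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  w0 = 1 - v - w; w1 = v; w2 = w;
  return A + ab * v + ac * w;
}

// penalty contact between surface vertices and non-neighbouring surface
// triangles; neighbourhood excluded by reference (material) distance r_skip.
// Potential: E = stiffness/2 * (margin - d)^2 per active pair
// [[Rcpp::export]]
List cpp_contact_forces(const arma::mat& x, const arma::mat& Xref,
                        const arma::imat& tris, const arma::ivec& verts,
                        double margin, double stiffness, double r_skip) {
  const int n = x.n_rows;
  double energy = 0.0;
  arma::mat forces(n, 3, arma::fill::zeros);
  if (tris.n_rows == 0 || verts.n_elem == 0 || margin <= 0)
    return List::create(_["forces"] = forces, _["energy"] = energy);
  SpatialHash hash;
  hash.cell = 2.0 * margin;
  for (arma::uword t = 0; t < tris.n_rows; ++t) {
    arma::vec3 A = x.row(tris(t, 0) - 1).t(), B = x.row(tris(t, 1) - 1).t(),
               C = x.row(tris(t, 2) - 1).t();
    arma::vec3 lo = arma::min(arma::min(A, B), C) - margin;
    arma::vec3 hi = arma::max(arma::max(A, B), C) + margin;
    hash.insert_box(lo, hi, int(t));
  }
  double r_skip2 = r_skip * r_skip;
  for (arma::uword vi = 0; vi < verts.n_elem; ++vi) {
    int v = verts(vi) - 1;
    arma::vec3 p = x.row(v).t(), P0 = Xref.row(v).t();
    const std::vector<int>* cand = hash.query(p);
    if (!cand) continue;
    for (int t : *cand) {
      int i0 = tris(t, 0) - 1, i1 = tris(t, 1) - 1, i2 = tris(t, 2) - 1;
      if (i0 == v || i1 == v || i2 == v) continue;
      // material-frame exclusion of the local neighbourhood
      double dm = std::min({arma::accu(arma::square(Xref.row(i0).t() - P0)),
                            arma::accu(arma::square(Xref.row(i1).t() - P0)),
                            arma::accu(arma::square(Xref.row(i2).t() - P0))});
      if (dm < r_skip2) continue;
      double w0, w1, w2;
      arma::vec3 c = closest_on_triangle(p, x.row(i0).t(), x.row(i1).t(),
                                         x.row(i2).t(), w0, w1, w2);
      arma::vec3 d = p - c;
      double dist = arma::norm(d);
      if (dist >= margin || dist < 1e-12) continue;
      arma::vec3 f = stiffness * (margin - dist) * (d / dist);
      energy += 0.5 * stiffness * (margin - dist) * (margin - dist);
      forces.row(v) += f.t();
      forces.row(i0) -= (w0 * f).t();
      forces.row(i1) -= (w1 * f).t();
      forces.row(i2) -= (w2 * f).t();
    }
  }
  return List::create(_["forces"] = forces, _["energy"] = energy);
}

// damped quasi-static relaxation with adaptive dt and energy-increase guard
// [[Rcpp::export]]
List cpp_relax(arma::mat x, const arma::imat& tets, const arma::cube& Bm,
               const arma::vec& vol, const arma::vec& mu, const arma::vec& K,
               const arma::vec& k1, const arma::vec& k2, const arma::mat& a1,
               const arma::mat& a2, const arma::cube& Fg,
               const arma::uvec& free_nodes, const arma::mat& Xref,
               const arma::imat& surf_tris, const arma::ivec& surf_verts,
               double contact_margin, double contact_stiffness,
               double contact_rskip, double dt0, double damping, double tol,
               int max_iter, int check_every) {
  arma::mat v(x.n_rows, 3, arma::fill::zeros);
  double dt = dt0;
  bool use_contact = surf_tris.n_rows > 0 && contact_margin > 0;
  auto eval = [&](const arma::mat& xx, arma::mat& f) -> double {
    List ef = cpp_energy_forces(xx, tets, Bm, vol, mu, K, k1, k2, a1, a2, Fg);
    f = as<arma::mat>(ef["forces"]);
    double E = as<double>(ef["energy"]);
    if (use_contact) {
      List cf = cpp_contact_forces(xx, Xref, surf_tris, surf_verts,
                                   contact_margin, contact_stiffness,
                                   contact_rskip);
      f += as<arma::mat>(cf["forces"]);
      E += as<double>(cf["energy"]);
    }
    return E;
  };
  arma::mat f;
  double E = eval(x, f);
  arma::mat x_snap = x; double E_snap = E;
  double fmax = 0.0;
  int it = 0, accepted_since_check = 0;
  for (it = 0; it < max_iter; ++it) {
    fmax = 0.0;
    for (arma::uword i = 0; i < free_nodes.n_elem; ++i) {
      double fn = arma::norm(f.row(free_nodes(i) - 1));
      if (fn > fmax) fmax = fn;
    }
    if (fmax < tol) break;
    // damped velocity update on free nodes only
    v *= (1.0 - damping);
    for (arma::uword i = 0; i < free_nodes.n_elem; ++i) {
      int nid = free_nodes(i) - 1;
      v.row(nid) += dt * f.row(nid);
    }
    arma::mat x_new = x;
    for (arma::uword i = 0; i < free_nodes.n_elem; ++i) {
      int nid = free_nodes(i) - 1;
      x_new.row(nid) += dt * v.row(nid);
    }
    arma::mat f_new;
    double E_new = eval(x_new, f_new);
    if (!std::isfinite(E_new) ||
        E_new > E_snap + 0.05 * std::abs(E_snap) + 1e-10) {
      // unstable: reject, restart from snapshot with halved dt
      x = x_snap; E = eval(x, f);
      v.zeros();
      dt *= 0.5;
      accepted_since_check = 0;
      if (dt < 1e-12 * dt0) break;
      continue;
    }
    x = x_new; E = E_new; f = f_new;
    if (++accepted_since_check >= check_every) {
      x_snap = x; E_snap = E;
      accepted_since_check = 0;
      dt = std::min(dt * 1.1, dt0 * 4.0);
    }
  }
  return List::create(_["x"] = x, _["energy"] = E, _["max_force"] = fmax,
                      _["iterations"] = it, _["converged"] = fmax < tol,
                      _["dt_final"] = dt);
}

// ---- triangle-triangle intersection audit (Moller 1997 style) ----

static bool tri_tri_overlap(const arma::vec3& a0, const arma::vec3& a1,
                            const arma::vec3& a2, const arma::vec3& b0,
                            const arma::vec3& b1, const arma::vec3& b2) {
  auto plane_dist = [](const arma::vec3& n, double d, const arma::vec3& p) {
    return arma::dot(n, p) + d;
  };
  arma::vec3 nA = arma::cross(a1 - a0, a2 - a0);
  double dA = -arma::dot(nA, a0);
  double db0 = plane_dist(nA, dA, b0), db1 = plane_dist(nA, dA, b1),
         db2 = plane_dist(nA, dA, b2);
  const double eps = 1e-12;
  if ((db0 > eps && db1 > eps && db2 > eps) ||
      (db0 < -eps && db1 < -eps && db2 < -eps)) return false;
  arma::vec3 nB = arma::cross(b1 - b0, b2 - b0);
  double dB = -arma::dot(nB, b0);
  double da0 = plane_dist(nB, dB, a0), da1 = plane_dist(nB, dB, a1),
         da2 = plane_dist(nB, dB, a2);
  if ((da0 > eps && da1 > eps && da2 > eps) ||
      (da0 < -eps && da1 < -eps && da2 < -eps)) return false;
  // project on the intersection line direction
  arma::vec3 D = arma::cross(nA, nB);
  int axis = arma::index_max(arma::abs(D));
  auto interval = [&](const arma::vec3& p0, const arma::vec3& p1,
                      const arma::vec3& p2, double d0, double d1, double d2,
                      double& t0, double& t1) -> bool {
    double p[3] = {p0(axis), p1(axis), p2(axis)};
    double d[3] = {d0, d1, d2};
    // find the vertex on the opposite side
    int iso = -1;
    if (d[0] * d[1] >= 0 && d[0] * d[2] >= 0) iso = 0;
    else if (d[1] * d[0] >= 0 && d[1] * d[2] >= 0) iso = 1;
    else iso = 2;
    int j = (iso + 1) % 3, k = (iso + 2) % 3;
    double denom1 = d[iso] - d[j], denom2 = d[iso] - d[k];
    if (std::abs(denom1) < eps || std::abs(denom2) < eps) return false;
    t0 = p[iso] + (p[j] - p[iso]) * d[iso] / denom1;
    t1 = p[iso] + (p[k] - p[iso]) * d[iso] / denom2;
    if (t0 > t1) std::swap(t0, t1);
    return true;
  };
  double s0, s1, t0, t1;
  if (!interval(a0, a1, a2, da0, da1, da2, s0, s1)) return false;
  if (!interval(b0, b1, b2, db0, db1, db2, t0, t1)) return false;
  return std::max(s0, t0) <= std::min(s1, t1);
}

// count intersecting non-neighbouring surface triangle pairs
// [[Rcpp::export]]
int cpp_self_intersections(const arma::mat& x, const arma::mat& Xref,
                           const arma::imat& tris, double r_skip,
                           double cell_size) {
  const int m = tris.n_rows;
  if (m == 0) return 0;
  SpatialHash hash;
  hash.cell = cell_size;
  std::vector<arma::vec3> lo(m), hi(m);
  for (int t = 0; t < m; ++t) {
    arma::vec3 A = x.row(tris(t, 0) - 1).t(), B = x.row(tris(t, 1) - 1).t(),
               C = x.row(tris(t, 2) - 1).t();
    lo[t] = arma::min(arma::min(A, B), C);
    hi[t] = arma::max(arma::max(A, B), C);
    hash.insert_box(lo[t], hi[t], t);
  }
  double r_skip2 = r_skip * r_skip;
  int count = 0;
  for (int t = 0; t < m; ++t) {
    std::vector<int> cands;
    arma::vec3 c = 0.5 * (lo[t] + hi[t]);
    // gather candidates from cells covered by this box
    for (int ix = int(std::floor(lo[t](0) / hash.cell)); ix <= int(std::floor(hi[t](0) / hash.cell)); ++ix)
      for (int iy = int(std::floor(lo[t](1) / hash.cell)); iy <= int(std::floor(hi[t](1) / hash.cell)); ++iy)
        for (int iz = int(std::floor(lo[t](2) / hash.cell)); iz <= int(std::floor(hi[t](2) / hash.cell)); ++iz) {
          auto it = hash.map.find(SpatialHash::key(ix, iy, iz));
          if (it != hash.map.end())
            cands.insert(cands.end(), it->second.begin(), it->second.end());
        }
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    for (int u : cands) {
      if (u <= t) continue;
      // shared vertices -> neighbours, skip
      bool shared = false;
      for (int i = 0; i < 3 && !shared; ++i)
        for (int j = 0; j < 3; ++j)
          if (tris(t, i) == tris(u, j)) { shared = true; break; }
      if (shared) continue;
      double dm = arma::datum::inf;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double d2 = arma::accu(arma::square(
            Xref.row(tris(t, i) - 1) - Xref.row(tris(u, j) - 1)));
          if (d2 < dm) dm = d2;
        }
      if (dm < r_skip2) continue;
      if (arma::any(lo[u] > hi[t]) || arma::any(hi[u] < lo[t])) continue;
      if (tri_tri_overlap(x.row(tris(t, 0) - 1).t(), x.row(tris(t, 1) - 1).t(),
                          x.row(tris(t, 2) - 1).t(), x.row(tris(u, 0) - 1).t(),
                          x.row(tris(u, 1) - 1).t(), x.row(tris(u, 2) - 1).t()))
        ++count;
    }
  }
  return count;
}
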