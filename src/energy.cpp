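// Strain-energy kernel for the passive ankle model.
//
// Total energy at generalized coordinates q (driver external rotation
// prescribed separately, radians):
//   E = sum_ligaments V(eps) + sum_joints 0.5 k |gap|^2
//       + 0.5 sum_i reg_i q_i^2 - extF . t_driver
// with the tension-only toe/linear ligament law
//   F = 0                        eps <= 0
//   F = k eps^2 / (4 eps_t)      0 < eps <= 2 eps_t
//   F = k (eps - eps_t)          eps > 2 eps_t,
//   eps = (L - L0)/L0 + eps0.
// The analytic gradient is returned alongside; the Hessian is a central
// finite difference of the analytic gradient.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Compiled {
  int nseg, ncoord, nlig, njnt, driver_seg;
  arma::imat layout;            // nseg x 6, 0-based coord index, -1 zero, -2 driver
  arma::ivec lig_oseg, lig_iseg, jnt_pseg, jnt_cseg;
  arma::mat lig_opts, lig_ipts, jnt_ppts, jnt_cpts;   // 3 x n
  arma::vec lig_L0, lig_k, lig_eps_t, lig_eps0, jnt_k;
  arma::mat jnt_c;  // 9 x njnt, column-stacked 3x3 capsule stiffness matrices
};

Compiled unpack(const List& C) {
  Compiled c;
  c.nseg = as<int>(C["nseg"]);
  c.ncoord = as<int>(C["ncoord"]);
  c.nlig = as<int>(C["nlig"]);
  c.njnt = as<int>(C["njnt"]);
  c.driver_seg = as<int>(C["driver_seg"]);
  c.layout = arma::conv_to<arma::imat>::from(
      as<arma::Mat<int>>(C["layout"]));
  c.lig_oseg = arma::conv_to<arma::ivec>::from(as<arma::Col<int>>(C["lig_oseg"]));
  c.lig_iseg = arma::conv_to<arma::ivec>::from(as<arma::Col<int>>(C["lig_iseg"]));
  c.jnt_pseg = arma::conv_to<arma::ivec>::from(as<arma::Col<int>>(C["jnt_pseg"]));
  c.jnt_cseg = arma::conv_to<arma::ivec>::from(as<arma::Col<int>>(C["jnt_cseg"]));
  c.lig_opts = as<arma::mat>(C["lig_opts"]);
  c.lig_ipts = as<arma::mat>(C["lig_ipts"]);
  c.jnt_ppts = as<arma::mat>(C["jnt_ppts"]);
  c.jnt_cpts = as<arma::mat>(C["jnt_cpts"]);
  c.lig_L0 = as<arma::vec>(C["lig_L0"]);
  c.lig_k = as<arma::vec>(C["lig_k"]);
  c.lig_eps_t = as<arma::vec>(C["lig_eps_t"]);
  c.lig_eps0 = as<arma::vec>(C["lig_eps0"]);
  c.jnt_k = as<arma::vec>(C["jnt_k"]);
  c.jnt_c = as<arma::mat>(C["jnt_c"]);
  return c;
}

void rot_z(double a, arma::mat33& R) {
  double c = std::cos(a), s = std::sin(a);
  R = {{c, -s, 0}, {s, c, 0}, {0, 0, 1}};
}
void rot_x(double a, arma::mat33& R) {
  double c = std::cos(a), s = std::sin(a);
  R = {{1, 0, 0}, {0, c, -s}, {0, s, c}};
}
void rot_ypos(double a, arma::mat33& R) {  // Ry(a)
  double c = std::cos(a), s = std::sin(a);
  R = {{c, 0, s}, {0, 1, 0}, {-s, 0, c}};
}
void drot_z(double a, arma::mat33& R) {
  double c = std::cos(a), s = std::sin(a);
  R = {{-s, -c, 0}, {c, -s, 0}, {0, 0, 0}};
}
void drot_x(double a, arma::mat33& R) {
  double c = std::cos(a), s = std::sin(a);
  R = {{0, 0, 0}, {0, -s, -c}, {0, c, -s}};
}
void drot_ypos(double a, arma::mat33& R) {  // d/da Ry(a)
  double c = std::cos(a), s = std::sin(a);
  R = {{-s, 0, c}, {0, 0, 0}, {-c, 0, -s}};
}

struct SegKin {
  arma::mat33 R;
  arma::mat33 dR[3];  // wrt angle slots a, b, c
  arma::vec3 t;
  bool fixed;
};

// angle/translation values for segment s from q / driver
inline double slot_val(const Compiled& c, const arma::vec& q, double er,
                       int s, int j) {
  int id = c.layout(s, j);
  if (id == -1) return 0.0;
  if (id == -2) return er;
  return q(id);
}

void seg_kinematics(const Compiled& c, const arma::vec& q, double er,
                    std::vector<SegKin>& K) {
  K.resize(c.nseg);
  for (int s = 0; s < c.nseg; ++s) {
    double a = slot_val(c, q, er, s, 0);
    double b = slot_val(c, q, er, s, 1);
    double cc = slot_val(c, q, er, s, 2);
    K[s].fixed = (c.layout(s, 0) == -1 && c.layout(s, 3) == -1 &&
                  c.layout(s, 2) != -2);
    arma::mat33 Rz, Rx, Ry, dRz, dRx, dRy;
    rot_z(a, Rz); rot_x(b, Rx); rot_ypos(cc, Ry);
    drot_z(a, dRz); drot_x(b, dRx); drot_ypos(cc, dRy);
    K[s].R = Rz * Rx * Ry;
    K[s].dR[0] = dRz * Rx * Ry;
    K[s].dR[1] = Rz * dRx * Ry;
    K[s].dR[2] = Rz * Rx * dRy;
    K[s].t = {slot_val(c, q, er, s, 3), slot_val(c, q, er, s, 4),
              slot_val(c, q, er, s, 5)};
  }
}

// accumulate generalized force f (world) acting at local point p of segment s
void accumulate(const Compiled& c, const std::vector<SegKin>& K, int s,
                const arma::vec3& p, const arma::vec3& f, arma::vec& grad,
                double& grad_er) {
  for (int j = 0; j < 3; ++j) {
    int id = c.layout(s, j);
    if (id == -1) continue;
    double g = arma::dot(f, K[s].dR[j] * p);
    if (id == -2) grad_er += g; else grad(id) += g;
  }
  for (int j = 3; j < 6; ++j) {
    int id = c.layout(s, j);
    if (id >= 0) grad(id) += f(j - 3);
  }
}

void eval_core(const Compiled& c, const arma::vec& q, double er,
               const arma::vec& reg, const arma::vec3& extF,
               double& energy, arma::vec& grad, double& grad_er,
               arma::vec* lig_len, arma::vec* lig_tension,
               arma::mat* jnt_gap) {
  std::vector<SegKin> K;
  seg_kinematics(c, q, er, K);
  energy = 0.0;
  grad.zeros(c.ncoord);
  grad_er = 0.0;

  for (int i = 0; i < c.nlig; ++i) {
    int so = c.lig_oseg(i), si = c.lig_iseg(i);
    arma::vec3 po = c.lig_opts.col(i), pi = c.lig_ipts.col(i);
    arma::vec3 wo = K[so].R * po + K[so].t;
    arma::vec3 wi = K[si].R * pi + K[si].t;
    arma::vec3 d = wo - wi;
    double L = arma::norm(d);
    double L0 = c.lig_L0(i), k = c.lig_k(i), et = c.lig_eps_t(i);
    double eps = (L - L0) / L0 + c.lig_eps0(i);
    double F = 0.0, V = 0.0;
    if (eps > 0.0 && k > 0.0) {
      if (eps <= 2.0 * et) {
        F = k * eps * eps / (4.0 * et);
        V = k * L0 * eps * eps * eps / (12.0 * et);
      } else {
        F = k * (eps - et);
        V = k * L0 * ((eps - et) * (eps - et) / 2.0 + et * et / 6.0);
      }
    }
    energy += V;
    if (lig_len) (*lig_len)(i) = L;
    if (lig_tension) (*lig_tension)(i) = F;
    if (F > 0.0 && L > 1e-12) {
      arma::vec3 u = d / L;         // insertion -> origin
      arma::vec3 f = F * u;         // dV/d(wo) = F u ; dV/d(wi) = -F u
      accumulate(c, K, so, po, f, grad, grad_er);
      accumulate(c, K, si, pi, -f, grad, grad_er);
    }
  }

  for (int i = 0; i < c.njnt; ++i) {
    int sp = c.jnt_pseg(i), sc = c.jnt_cseg(i);
    arma::vec3 pp = c.jnt_ppts.col(i), pc = c.jnt_cpts.col(i);
    arma::vec3 wp = K[sp].R * pp + K[sp].t;
    arma::vec3 wc = K[sc].R * pc + K[sc].t;
    arma::vec3 g = wp - wc;
    energy += 0.5 * c.jnt_k(i) * arma::dot(g, g);
    if (jnt_gap) jnt_gap->col(i) = g;
    arma::vec3 f = c.jnt_k(i) * g;
    accumulate(c, K, sp, pp, f, grad, grad_er);
    accumulate(c, K, sc, pc, -f, grad, grad_er);
  }

  // capsule restraint: quadratic form 0.5 d^T C d on the difference d of
  // the parent and child Euler angle coordinates (small-relative-rotation
  // model); C may be non-diagonal to encode an oblique anatomical axis
  for (int i = 0; i < c.njnt; ++i) {
    arma::mat33 Cc(c.jnt_c.colptr(i));
    if (arma::norm(Cc, "fro") <= 0.0) continue;
    int sp = c.jnt_pseg(i), sc = c.jnt_cseg(i);
    arma::vec3 d;
    for (int j = 0; j < 3; ++j) {
      d(j) = slot_val(c, q, er, sp, j) - slot_val(c, q, er, sc, j);
    }
    energy += 0.5 * arma::dot(d, Cc * d);
    arma::vec3 t = Cc * d;
    for (int j = 0; j < 3; ++j) {
      int idp = c.layout(sp, j), idc = c.layout(sc, j);
      if (idp == -2) grad_er += t(j); else if (idp >= 0) grad(idp) += t(j);
      if (idc == -2) grad_er -= t(j); else if (idc >= 0) grad(idc) -= t(j);
    }
  }

  for (int i = 0; i < c.ncoord; ++i) {
    energy += 0.5 * reg(i) * q(i) * q(i);
    grad(i) += reg(i) * q(i);
  }

  // external dead load on the driver segment's frame origin
  if (arma::norm(extF) > 0.0) {
    int s = c.driver_seg;
    energy -= arma::dot(extF, K[s].t);
    for (int j = 3; j < 6; ++j) {
      int id = c.layout(s, j);
      if (id >= 0) grad(id) -= extF(j - 3);
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List perankle_eval(const arma::vec& q, double er_rad, const List& compiled,
                   const arma::vec& reg, const arma::vec& ext_force,
                   bool detail = false) {
  Compiled c = unpack(compiled);
  double energy, grad_er;
  arma::vec grad;
  arma::vec3 extF = {ext_force(0), ext_force(1), ext_force(2)};
  if (detail) {
    arma::vec len(std::max(c.nlig, 1)), ten(std::max(c.nlig, 1));
    arma::mat gap(3, std::max(c.njnt, 1), arma::fill::zeros);
    eval_core(c, q, er_rad, reg, extF, energy, grad, grad_er,
              &len, &ten, &gap);
    return List::create(_["energy"] = energy, _["grad"] = grad,
                        _["grad_er"] = grad_er,
                        _["lig_length"] = len.head(std::max(c.nlig, 0)),
                        _["lig_tension"] = ten.head(std::max(c.nlig, 0)),
                        _["jnt_gap"] = gap);
  }
  eval_core(c, q, er_rad, reg, extF, energy, grad, grad_er,
            nullptr, nullptr, nullptr);
  return List::create(_["energy"] = energy, _["grad"] = grad,
                      _["grad_er"] = grad_er);
}

// [[Rcpp::export]]
arma::mat perankle_hessian(const arma::vec& q, double er_rad,
                           const List& compiled, const arma::vec& reg,
                           const arma::vec& ext_force, double h = 1e-6) {
  Compiled c = unpack(compiled);
  arma::vec3 extF = {ext_force(0), ext_force(1), ext_force(2)};
  int n = c.ncoord;
  arma::mat H(n, n);
  arma::vec qp, gp, gm;
  double e, ger;
  for (int j = 0; j < n; ++j) {
    qp = q; qp(j) += h;
    eval_core(c, qp, er_rad, reg, extF, e, gp, ger, nullptr, nullptr, nullptr);
    qp(j) = q(j) - h;
    eval_core(c, qp, er_rad, reg, extF, e, gm, ger, nullptr, nullptr, nullptr);
    H.col(j) = (gp - gm) / (2.0 * h);
  }
  return 0.5 * (H + H.t());  // symmetrize
}
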