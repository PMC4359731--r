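// Core dynamics of the planar multilink swimming rod.
//
// The body is N rigid links of equal length joined end-to-end; generalized
// coordinates are the head endpoint (x, y) and the N link angles, so the
// inextensibility/unshearability constraints hold exactly by construction.
// Joints carry linear viscoelastic moments plus antagonist muscle moments;
// external forces are Taylor resistive fluid forces integrated along each
// link by 3-point Gauss quadrature (which also yields the spin torque).
//
// State vector layout (length 2*(N+2) + 2*nm):
//   y[0..1]            head position (m)
//   y[2..N+1]          link angles phi (rad)
//   y[N+2..N+3]        head velocity (m/s)
//   y[N+4..2N+3]       link angular velocities (rad/s)
//   y[2N+4..2N+3+nm]   left-side bound-calcium levels, muscle joints
//   y[..+nm]           right-side bound-calcium levels
//
// Equations of motion (Euler-Lagrange in the generalized coordinates):
//   [ m_tot I2   B ] [a_h  ]   [ Q_h + sum_j b_j e_j phidot_j^2          ]
//   [ B^T   Mpp+I ] [phidd] = [ Q_phi - sum_k A_jk sin(phi_j-phi_k) w_k^2]
// with B_:j = b_j n_j, Mpp_jk = A_jk cos(phi_j - phi_k),
// b_j = ell (S_{j+1} + m_j/2), A_jk = ell^2 (S_{k+1} + m_k/2) for j < k
// and ell^2 (S_{j+1} + m_j/4) on the diagonal, S_j = sum_{i>=j} m_i.

#include <RcppArmadillo.h>
#include <R_ext/Lapack.h>
using namespace arma;

struct RodContext {
  int N, nm;
  double ell;
  double mtot;
  vec m, Iz;
  vec wbar, sj;          // all joints, 0-based j = 0..N-2
  uvec jm;               // 0-based indices of muscle-bearing joints
  double kb, cb;
  vec P0;
  double kon, koff, gamma_w;
  double flw, aP0, vmax, ecc, pec_gain, pec_slack;
  double freq, duty, samp, ramp_rate, edge;
  bool mirror, act_on;
  double rho, CN, CT, height;
  mat perim_g;           // N x 3
  bool fluid_on;
  vec b;
  mat Aamp;
  // workspace (mutable across calls)
  vec cphi, sphi, vcx, vcy, Ffx, Ffy, tau, Mjoint, Qphi, pd2;
  vec u1, u2, r, acc, w1, w2;
  mat M;
  vec stimL, stimR, FL, FR, LL, LR, vL, vR, dcL, dcR;
};

static const double GX[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
static const double GW[3] = {0.5555555555555556, 0.8888888888888888,
                             0.5555555555555556};

// smoothed unit square pulse on the cyclic phase x in [0,1)
static inline double pulse(double x, double duty, double edge) {
  if (edge <= 0.0) return (x >= 0.0 && x < duty) ? 1.0 : 0.0;
  double v = 0.0;
  for (int k = -1; k <= 1; ++k) {
    double z = x + k;
    v += 0.5 * (std::tanh(z / edge) - std::tanh((z - duty) / edge));
  }
  return v;
}

static inline double fracpart(double x) { return x - std::floor(x); }

static inline double stim_level(const RodContext& C, double s, double t,
                                int side) {
  if (!C.act_on || t < 0.0) return 0.0;
  int sd = C.mirror ? 1 - side : side;
  double x = fracpart(C.freq * t - s + (sd == 1 ? 0.5 : 0.0));
  double ramp = std::tanh(C.ramp_rate * t);
  return C.samp * ramp * pulse(x, C.duty, C.edge);
}

static inline double fl_curve(double strain, double flw) {
  double z = strain / flw;
  return std::exp(-z * z);
}

// v in optimal lengths per second, positive shortening
static inline double fv_curve(double v, const RodContext& C) {
  double vh = v / C.vmax;
  if (vh >= 1.0) return 0.0;
  if (vh >= 0.0) return (1.0 - vh) / (1.0 + vh / C.aP0);
  double u = -vh;
  double ke = (C.ecc - 1.0) * C.aP0 / (C.aP0 + 1.0);
  return 1.0 + (C.ecc - 1.0) * u / (ke + u);
}

static void rod_compute(RodContext& C, double t, const double* y) {
  const int N = C.N, nm = C.nm;
  const double ell = C.ell;
  const double* phi = y + 2;
  const double vxh = y[N + 2], vyh = y[N + 3];
  const double* pd = y + N + 4;
  const double* cLv = y + 2 * N + 4;
  const double* cRv = y + 2 * N + 4 + nm;

  double* cc = C.cphi.memptr();
  double* ss = C.sphi.memptr();
  for (int i = 0; i < N; ++i) { cc[i] = std::cos(phi[i]);
                                ss[i] = std::sin(phi[i]); }

  // link centre velocities
  double accx = 0.0, accy = 0.0;
  for (int i = 0; i < N; ++i) {
    double tsi = ss[i] * pd[i], tci = cc[i] * pd[i];
    C.vcx(i) = vxh - (accx + 0.5 * ell * tsi);
    C.vcy(i) = vyh + (accy + 0.5 * ell * tci);
    accx += ell * tsi;
    accy += ell * tci;
  }

  // fluid forces: Taylor resistive density integrated along each link
  if (C.fluid_on) {
    const double cN = 0.5 * C.rho * C.CN * C.height;
    const double cT = 0.5 * C.rho * C.CT;
    for (int i = 0; i < N; ++i) {
      double Fx = 0, Fy = 0, Tq = 0;
      for (int g = 0; g < 3; ++g) {
        double xi = 0.5 * ell * GX[g];
        double wq = 0.5 * ell * GW[g];
        double vx = C.vcx(i) - xi * pd[i] * ss[i];
        double vy = C.vcy(i) + xi * pd[i] * cc[i];
        double vT = vx * cc[i] + vy * ss[i];
        double vN = -vx * ss[i] + vy * cc[i];
        double sp = std::sqrt(vT * vT + vN * vN);
        double fN = -cN * vN * std::abs(vN);
        double fT = -cT * C.perim_g(i, g) * vT * sp;
        Fx += wq * (fT * cc[i] - fN * ss[i]);
        Fy += wq * (fT * ss[i] + fN * cc[i]);
        Tq += wq * xi * fN;
      }
      C.Ffx(i) = Fx; C.Ffy(i) = Fy; C.tau(i) = Tq;
    }
  } else {
    C.Ffx.zeros(); C.Ffy.zeros(); C.tau.zeros();
  }

  // joint moments: passive viscoelastic everywhere, muscle where present
  for (int j = 0; j < N - 1; ++j) {
    C.Mjoint(j) = -C.kb * (phi[j + 1] - phi[j])
                - C.cb * (pd[j + 1] - pd[j]);
  }
  const double Lopt = ell;
  for (int k = 0; k < nm; ++k) {
    int j = C.jm(k);
    double dphi = phi[j + 1] - phi[j];
    double dphidot = pd[j + 1] - pd[j];
    double wb = C.wbar(j);
    C.LL(k) = ell - wb * dphi;   C.vL(k) = wb * dphidot;
    C.LR(k) = ell + wb * dphi;   C.vR(k) = -wb * dphidot;
    C.stimL(k) = stim_level(C, C.sj(j), t, 0);
    C.stimR(k) = stim_level(C, C.sj(j), t, 1);
    double fl = fl_curve(C.LL(k) / Lopt - 1.0, C.flw) *
                fv_curve(C.vL(k) / Lopt, C);
    double fr = fl_curve(C.LR(k) / Lopt - 1.0, C.flw) *
                fv_curve(C.vR(k) / Lopt, C);
    double actL = std::max(0.0, C.P0(k) * cLv[k] * fl);
    double actR = std::max(0.0, C.P0(k) * cRv[k] * fr);
    // parallel elastic component: quadratic toe spring beyond slack strain
    double sL = std::max(0.0, C.LL(k) / Lopt - 1.0 - C.pec_slack);
    double sR = std::max(0.0, C.LR(k) / Lopt - 1.0 - C.pec_slack);
    C.FL(k) = actL + C.pec_gain * C.P0(k) * sL * sL;
    C.FR(k) = actR + C.pec_gain * C.P0(k) * sR * sR;
    C.Mjoint(j) += (C.FL(k) - C.FR(k)) * wb;
    // only active force consumes activation through shortening work
    C.dcL(k) = C.kon * C.stimL(k) * (1.0 - cLv[k]) - C.koff * cLv[k]
             - C.gamma_w * cLv[k] * std::max(0.0, actL * C.vL(k));
    C.dcR(k) = C.kon * C.stimR(k) * (1.0 - cRv[k]) - C.koff * cRv[k]
             - C.gamma_w * cRv[k] * std::max(0.0, actR * C.vR(k));
  }

  // generalized forces
  double Qx = 0, Qy = 0;
  for (int i = 0; i < N; ++i) { Qx += C.Ffx(i); Qy += C.Ffy(i); }
  double sfx = 0.0, sfy = 0.0;
  for (int j = N - 1; j >= 0; --j) {
    double px = ell * sfx + 0.5 * ell * C.Ffx(j);
    double py = ell * sfy + 0.5 * ell * C.Ffy(j);
    C.Qphi(j) = -ss[j] * px + cc[j] * py + C.tau(j);
    sfx += C.Ffx(j);
    sfy += C.Ffy(j);
  }
  for (int j = 0; j < N - 1; ++j) {
    C.Qphi(j)     -= C.Mjoint(j);
    C.Qphi(j + 1) += C.Mjoint(j);
  }

  // assemble and solve the (N+2) x (N+2) system
  for (int j = 0; j < N; ++j) {
    C.pd2(j) = pd[j] * pd[j];
    C.w1(j) = cc[j] * C.pd2(j);    // cos phi * phidot^2
    C.w2(j) = ss[j] * C.pd2(j);
  }
  C.u1 = C.Aamp * C.w1;            // sum_k A_jk cos(phi_k) phidot_k^2
  C.u2 = C.Aamp * C.w2;

  double rx = Qx, ry = Qy;
  for (int j = 0; j < N; ++j) {
    rx += C.b(j) * C.w1(j);
    ry += C.b(j) * C.w2(j);
  }
  C.r(0) = rx; C.r(1) = ry;
  for (int j = 0; j < N; ++j) {
    // sin(phi_j - phi_k) = s_j c_k - c_j s_k
    C.r(2 + j) = C.Qphi(j) - (ss[j] * C.u1(j) - cc[j] * C.u2(j));
  }

  // upper triangle only; solved in place by Cholesky (LAPACK dposv)
  mat& M = C.M;
  M(0, 0) = C.mtot; M(1, 1) = C.mtot; M(0, 1) = 0.0;
  for (int j = 0; j < N; ++j) {
    M(0, 2 + j) = -C.b(j) * ss[j];
    M(1, 2 + j) = C.b(j) * cc[j];
  }
  for (int k = 0; k < N; ++k) {
    double* col = M.colptr(2 + k);
    for (int j = 0; j < k; ++j) {
      col[2 + j] = C.Aamp(j, k) * (cc[j] * cc[k] + ss[j] * ss[k]);
    }
    col[2 + k] = C.Aamp(k, k) + C.Iz(k);
  }
  std::memcpy(C.acc.memptr(), C.r.memptr(), (N + 2) * sizeof(double));
  int dim = N + 2, one = 1, info = 0;
  F77_CALL(dposv)("U", &dim, &one, M.memptr(), &dim, C.acc.memptr(),
                  &dim, &info FCONE);
  if (info != 0) C.acc.fill(datum::nan);
}

static void fill_deriv(const RodContext& C, const double* y, double* dy) {
  int N = C.N, nm = C.nm;
  dy[0] = y[N + 2];
  dy[1] = y[N + 3];
  for (int j = 0; j < N; ++j) dy[2 + j] = y[N + 4 + j];
  for (int i = 0; i < N + 2; ++i) dy[N + 2 + i] = C.acc(i);
  for (int k = 0; k < nm; ++k) {
    dy[2 * N + 4 + k] = C.dcL(k);
    dy[2 * N + 4 + nm + k] = C.dcR(k);
  }
}

static RodContext* g_ctx = nullptr;

// [[Rcpp::export]]
SEXP rod_context(Rcpp::List spec) {
  RodContext* C = new RodContext();
  C->N = Rcpp::as<int>(spec["n"]);
  C->ell = Rcpp::as<double>(spec["ell"]);
  C->m = Rcpp::as<vec>(spec["mass"]);
  C->mtot = accu(C->m);
  C->Iz = Rcpp::as<vec>(spec["inertia"]);
  C->wbar = Rcpp::as<vec>(spec["wbar"]);
  C->sj = Rcpp::as<vec>(spec["s_joint"]);
  C->jm = Rcpp::as<uvec>(spec["muscle_joints"]);  // already 0-based
  C->nm = C->jm.n_elem;
  C->kb = Rcpp::as<double>(spec["kb"]);
  C->cb = Rcpp::as<double>(spec["cb"]);
  C->P0 = Rcpp::as<vec>(spec["P0"]);
  C->kon = Rcpp::as<double>(spec["k_on"]);
  C->koff = Rcpp::as<double>(spec["k_off"]);
  C->gamma_w = Rcpp::as<double>(spec["gamma_wdd"]);
  C->flw = Rcpp::as<double>(spec["fl_width"]);
  C->aP0 = Rcpp::as<double>(spec["a_p0"]);
  C->vmax = Rcpp::as<double>(spec["v_max"]);
  C->ecc = Rcpp::as<double>(spec["ecc_plateau"]);
  C->pec_gain = Rcpp::as<double>(spec["pec_gain"]);
  C->pec_slack = Rcpp::as<double>(spec["pec_slack"]);
  C->freq = Rcpp::as<double>(spec["freq"]);
  C->duty = Rcpp::as<double>(spec["duty"]);
  C->samp = Rcpp::as<double>(spec["stim_amp"]);
  C->ramp_rate = Rcpp::as<double>(spec["ramp_rate"]);
  C->edge = Rcpp::as<double>(spec["edge"]);
  C->mirror = Rcpp::as<bool>(spec["mirror"]);
  C->act_on = Rcpp::as<bool>(spec["act_on"]);
  C->rho = Rcpp::as<double>(spec["rho"]);
  C->CN = Rcpp::as<double>(spec["c_n"]);
  C->CT = Rcpp::as<double>(spec["c_t"]);
  C->height = Rcpp::as<double>(spec["height"]);
  C->perim_g = Rcpp::as<mat>(spec["perim_g"]);
  C->fluid_on = Rcpp::as<bool>(spec["fluid_on"]);

  int N = C->N, nm = C->nm;
  vec S(N + 1, fill::zeros);           // S(j) = sum_{i >= j} m_i
  for (int j = N - 1; j >= 0; --j) S(j) = S(j + 1) + C->m(j);
  C->b.set_size(N);
  C->Aamp.set_size(N, N);
  for (int j = 0; j < N; ++j) {
    C->b(j) = C->ell * (S(j + 1) + 0.5 * C->m(j));
    for (int k = j; k < N; ++k) {
      double a = (j == k)
        ? C->ell * C->ell * (S(k + 1) + 0.25 * C->m(k))
        : C->ell * C->ell * (S(k + 1) + 0.5 * C->m(k));
      C->Aamp(j, k) = a;
      C->Aamp(k, j) = a;
    }
  }
  C->cphi.set_size(N); C->sphi.set_size(N);
  C->vcx.set_size(N); C->vcy.set_size(N);
  C->Ffx.set_size(N); C->Ffy.set_size(N); C->tau.set_size(N);
  C->Mjoint.set_size(std::max(N - 1, 1)); C->Qphi.set_size(N);
  C->pd2.set_size(N); C->u1.set_size(N); C->u2.set_size(N);
  C->w1.set_size(N); C->w2.set_size(N);
  C->r.set_size(N + 2); C->acc.set_size(N + 2);
  C->M.zeros(N + 2, N + 2);
  int nz = std::max(nm, 1);
  C->stimL.zeros(nz); C->stimR.zeros(nz);
  C->FL.zeros(nz); C->FR.zeros(nz);
  C->LL.zeros(nz); C->LR.zeros(nz);
  C->vL.zeros(nz); C->vR.zeros(nz);
  C->dcL.zeros(nz); C->dcR.zeros(nz);

  Rcpp::XPtr<RodContext> xp(C, true);
  return xp;
}

// install the context used by the native deSolve entry point
// [[Rcpp::export]]
void rod_use_context(SEXP xp) {
  Rcpp::XPtr<RodContext> p(xp);
  g_ctx = p.get();
}

// deSolve resolves the native derivative below by name at run time
// [[Rcpp::init]]
void rod_core_init(DllInfo* dll) {
  R_useDynamicSymbols(dll, TRUE);
}

extern "C" void rod_deriv_native(int* neq, double* t, double* y,
                                 double* ydot, double* yout, int* ip) {
  (void)neq; (void)yout; (void)ip;
  rod_compute(*g_ctx, *t, y);
  fill_deriv(*g_ctx, y, ydot);
}

// [[Rcpp::export]]
Rcpp::NumericVector rod_deriv(double t, Rcpp::NumericVector y, SEXP xp) {
  Rcpp::XPtr<RodContext> p(xp);
  RodContext& C = *p;
  if ((int)y.size() != 2 * (C.N + 2) + 2 * C.nm)
    Rcpp::stop("state vector has wrong length");
  rod_compute(C, t, y.begin());
  Rcpp::NumericVector dy(y.size());
  fill_deriv(C, y.begin(), dy.begin());
  return dy;
}

// [[Rcpp::export]]
Rcpp::List rod_snapshot(double t, Rcpp::NumericVector y, SEXP xp) {
  Rcpp::XPtr<RodContext> p(xp);
  RodContext& C = *p;
  if ((int)y.size() != 2 * (C.N + 2) + 2 * C.nm)
    Rcpp::stop("state vector has wrong length");
  rod_compute(C, t, y.begin());
  int nm = C.nm;
  auto take = [nm](const vec& v) {
    return Rcpp::NumericVector(v.begin(), v.begin() + nm);
  };
  return Rcpp::List::create(
    Rcpp::Named("stim_l") = take(C.stimL),
    Rcpp::Named("stim_r") = take(C.stimR),
    Rcpp::Named("force_l") = take(C.FL),
    Rcpp::Named("force_r") = take(C.FR),
    Rcpp::Named("len_l") = take(C.LL),
    Rcpp::Named("len_r") = take(C.LR),
    Rcpp::Named("vel_l") = take(C.vL),
    Rcpp::Named("vel_r") = take(C.vR),
    Rcpp::Named("fluid_fx") = C.Ffx,
    Rcpp::Named("fluid_fy") = C.Ffy,
    Rcpp::Named("fluid_tau") = C.tau,
    Rcpp::Named("joint_moment") = C.Mjoint,
    Rcpp::Named("acc") = C.acc);
}
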