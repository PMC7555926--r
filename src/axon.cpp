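// Core numerics for the two-compartment (node + internode) axon model.
//
// State vector layout (all voltages mV, gates dimensionless in [0,1]):
//   0 V_n, 1 V_i, 2 m, 3 h, 4 p, 5 s_n, 6 s_i, 7 n_f, 8 q
//
// Parameter vector layout (see pack_axon_params() on the R side):
//   0 C_n, 1 C_i, 2 G_NaT, 3 f_NaP, 4 G_Ks_n, 5 G_Ks_i, 6 G_Kf_n,
//   7 G_Kf_i, 8 G_H, 9 G_Lk_n, 10 G_Lk_i, 11 G_BB, 12 E_Na, 13 E_K,
//   14 E_H, 15 E_Lk, 16 I_pump, 17 f_pump_node, 18 T, 19 T_ref,
//   20 k_EK_pump (mV/pA), 21 I_pump_ref (pA), 22 f_K_leak_i
//
// Periaxonal potassium coupling: the space under the myelin is cleared by
// the pump, so a standing pump deficit depolarizes the potassium reversal
// seen by the internodal channels (steady-state surrogate, no
// concentration dynamics): dEK = k_EK_pump * (I_pump_ref - I_pump),
// applied fully to the internodal K channels and to the fraction
// f_K_leak_i of the internodal leak.
//
// Rate-coefficient matrix: 14 rows (alpha then beta for each of the seven
// gates m, h, p, s_n, s_i, n_f, q), columns form, A, B, C.  Forms:
//   1 linoid (rising):  A*(V-B)/(1 - exp(-(V-B)/C))
//   2 exponential:      A*exp((V-B)/C)
//   3 sigmoid:          A/(1 + exp(-(V-B)/C))
//   4 linoid (falling): A*(B-V)/(1 - exp(-(B-V)/C))
//
// Units are self-consistent: pA = nS * mV, ms = pF / nS.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 9;
static const int NGATE = 7;

// voltage source per gate: 0 -> V_n, 1 -> V_i
static const int GATE_VSRC[NGATE] = {0, 0, 0, 0, 1, 0, 1};

static inline double rate_eval(int form, double A, double B, double C,
                               double V) {
  double x, r;
  switch (form) {
  case 1:  // rising linoid; analytic limit A*C at V == B
    x = V - B;
    if (std::fabs(x) < 1e-7 * std::fabs(C))
      r = A * (C + 0.5 * x);
    else
      r = A * x / (1.0 - std::exp(-x / C));
    break;
  case 2: {
    double e = (V - B) / C;
    if (e > 60.0) e = 60.0;  // overflow guard for wild trial states
    r = A * std::exp(e);
    break;
  }
  case 3:
    r = A / (1.0 + std::exp(-(V - B) / C));
    break;
  case 4:  // falling linoid; analytic limit A*C at V == B
    x = B - V;
    if (std::fabs(x) < 1e-7 * std::fabs(C))
      r = A * (C + 0.5 * x);
    else
      r = A * x / (1.0 - std::exp(-x / C));
    break;
  default:
    stop("unknown rate functional form code %d", form);
  }
  return r > 0.0 ? r : 0.0;
}

struct AxonSystem {
  const double *p;      // parameter vector
  const double *rc;     // 14 x 4 rate matrix, column-major
  const double *q10;    // per-gate Q10
  int rc_nrow;
  double tau_floor;     // smooth lower bound on gate time constants, ms
  double tfac;          // (T - T_ref) / 10

  void rates(int g, double V, double &a, double &b) const {
    const int ra = 2 * g, rb = 2 * g + 1;
    double phi = std::pow(q10[g], tfac);
    a = phi * rate_eval((int)rc[ra], rc[ra + rc_nrow],
                        rc[ra + 2 * rc_nrow], rc[ra + 3 * rc_nrow], V);
    b = phi * rate_eval((int)rc[rb], rc[rb + rc_nrow],
                        rc[rb + 2 * rc_nrow], rc[rb + 3 * rc_nrow], V);
    if (tau_floor > 0.0) {
      double sc = 1.0 / (1.0 + (a + b) * tau_floor);
      a *= sc;
      b *= sc;
    }
  }

  void rhs(const double *y, double istim, double *dy) const {
    const double Vn = y[0], Vi = y[1];
    const double m = y[2], h = y[3], pp = y[4], sn = y[5], si = y[6],
                 nf = y[7], q = y[8];
    const double m3 = m * m * m, p3 = pp * pp * pp,
                 nf4 = nf * nf * nf * nf;

    const double i_nat = p[2] * m3 * h * (Vn - p[12]);
    const double i_nap = p[2] * p[3] * p3 * (Vn - p[12]);
    const double i_ksn = p[4] * sn * (Vn - p[13]);
    const double i_kfn = p[6] * nf4 * (Vn - p[13]);
    const double i_lkn = p[9] * (Vn - p[15]);
    const double i_pn = p[17] * p[16];
    const double i_bb = p[11] * (Vn - Vi);

    const double dek = p[20] * (p[21] - p[16]);
    const double ek_i = p[13] + dek;
    const double elk_i = p[15] + p[22] * dek;
    const double i_ksi = p[5] * si * (Vi - ek_i);
    const double i_kfi = p[7] * nf4 * (Vi - ek_i);
    const double i_h = p[8] * q * (Vi - p[14]);
    const double i_lki = p[10] * (Vi - elk_i);
    const double i_pi = (1.0 - p[17]) * p[16];

    dy[0] = (-(i_nat + i_nap + i_ksn + i_kfn + i_lkn + i_pn) - i_bb +
             istim) / p[0];
    dy[1] = (-(i_ksi + i_kfi + i_h + i_lki + i_pi) + i_bb) / p[1];

    for (int g = 0; g < NGATE; ++g) {
      double a, b;
      rates(g, GATE_VSRC[g] == 0 ? Vn : Vi, a, b);
      double x = y[2 + g];
      dy[2 + g] = a * (1.0 - x) - b * x;
    }
  }
};

// Dormand-Prince 5(4) coefficients
static const double DP_C[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0,
                               1.0};
static const double DP_A[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
    {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
    {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
    {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176,
     -5103.0 / 18656, 0},
    {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double DP_B5[7] = {35.0 / 384,      0, 500.0 / 1113,
                                125.0 / 192,     -2187.0 / 6784,
                                11.0 / 84,       0};
static const double DP_B4[7] = {5179.0 / 57600,  0, 7571.0 / 16695,
                                393.0 / 640,     -92097.0 / 339200,
                                187.0 / 2100,    1.0 / 40};

// [[Rcpp::export]]
NumericVector cpp_rhs(NumericVector y, NumericVector pvec,
                      NumericMatrix rates, NumericVector q10,
                      double istim = 0.0, double tau_floor = 0.0) {
  if (y.size() != NSTATE) stop("state vector must have length 9");
  AxonSystem sys;
  sys.p = pvec.begin();
  sys.rc = rates.begin();
  sys.q10 = q10.begin();
  sys.rc_nrow = rates.nrow();
  sys.tau_floor = tau_floor;
  sys.tfac = (pvec[18] - pvec[19]) / 10.0;
  NumericVector dy(NSTATE);
  sys.rhs(y.begin(), istim, dy.begin());
  return dy;
}

// [[Rcpp::export]]
NumericVector cpp_gate_rates(int gate, NumericVector V, NumericMatrix rates,
                             NumericVector q10, double tfac,
                             double tau_floor = 0.0) {
  // returns c(alpha..., beta...) stacked, for one gate over a voltage grid
  const int n = V.size();
  NumericVector out(2 * n);
  const double *rc = rates.begin();
  const int nr = rates.nrow();
  const int ra = 2 * (gate - 1), rb = ra + 1;
  double phi = std::pow(q10[gate - 1], tfac);
  for (int i = 0; i < n; ++i) {
    double a = phi * rate_eval((int)rc[ra], rc[ra + nr], rc[ra + 2 * nr],
                               rc[ra + 3 * nr], V[i]);
    double b = phi * rate_eval((int)rc[rb], rc[rb + nr], rc[rb + 2 * nr],
                               rc[rb + 3 * nr], V[i]);
    if (tau_floor > 0.0) {
      double sc = 1.0 / (1.0 + (a + b) * tau_floor);
      a *= sc;
      b *= sc;
    }
    out[i] = a;
    out[n + i] = b;
  }
  return out;
}

// Adaptive Dormand-Prince integration with a piecewise-constant nodal
// stimulus.  Steps are forced to land on stimulus edges; step size is
// capped near edges and during suprathreshold excursions so that action
// potentials cannot be stepped over.  Upward crossings of V_n through
// 0 mV are located by linear interpolation within the accepted step.
// [[Rcpp::export]]
List cpp_integrate(NumericVector y0, NumericVector pvec, NumericMatrix rates,
                   NumericVector q10, NumericVector stim_t,
                   NumericVector stim_a, double t_end, double dt_max,
                   double rtol, double tau_floor, bool record,
                   double watch_from, double watch_to) {
  if (y0.size() != NSTATE) stop("state vector must have length 9");
  if (t_end <= 0) stop("t_end must be positive");
  const int nseg = stim_t.size();
  AxonSystem sys;
  sys.p = pvec.begin();
  sys.rc = rates.begin();
  sys.q10 = q10.begin();
  sys.rc_nrow = rates.nrow();
  sys.tau_floor = tau_floor;
  sys.tfac = (pvec[18] - pvec[19]) / 10.0;

  double y[NSTATE], ynew[NSTATE], yerr[NSTATE];
  double k[7][NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  const double atolV = 1e-6, atolG = 1e-9;
  double t = 0.0, dt = std::min(dt_max, 1e-3);
  int seg = 0;
  while (seg < nseg && stim_t[seg] <= t + 1e-12) ++seg;
  // seg is index of next upcoming edge; active amplitude is stim_a[seg-1]
  std::vector<double> crossings;
  double vmax = -1e30;
  std::vector<double> traj;
  long nstep = 0, nreject = 0;

  if (record) {
    traj.push_back(t);
    for (int i = 0; i < NSTATE; ++i) traj.push_back(y[i]);
  }
  if (t >= watch_from && t <= watch_to && y[0] > vmax) vmax = y[0];

  while (t < t_end - 1e-12) {
    double amp = (seg > 0) ? stim_a[seg - 1] : 0.0;
    double next_stop = (seg < nseg) ? std::min(stim_t[seg], t_end) : t_end;

    double cap = dt_max;
    // fine resolution during and shortly after any stimulus edge when a
    // dense trajectory is requested (AP detection contract)
    if (record) {
      for (int j = 0; j < nseg; ++j)
        if (t >= stim_t[j] - 1e-12 && t < stim_t[j] + 3.0) cap =
            std::min(cap, 0.01);
    }
    if (y[0] > -40.0) cap = std::min(cap, 0.02);  // spike upstroke guard
    dt = std::min(dt, cap);
    if (t + dt > next_stop) dt = next_stop - t;
    if (dt < 1e-12) {
      t = next_stop;
      while (seg < nseg && stim_t[seg] <= t + 1e-12) ++seg;
      dt = 1e-3;
      continue;
    }

    // Dormand-Prince step
    sys.rhs(y, amp, k[0]);
    for (int s = 1; s < 7; ++s) {
      double ytmp[NSTATE];
      for (int i = 0; i < NSTATE; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += DP_A[s][j] * k[j][i];
        ytmp[i] = y[i] + dt * acc;
      }
      sys.rhs(ytmp, amp, k[s]);
    }
    double err = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double acc5 = 0.0, acc4 = 0.0;
      for (int s = 0; s < 7; ++s) {
        acc5 += DP_B5[s] * k[s][i];
        acc4 += DP_B4[s] * k[s][i];
      }
      ynew[i] = y[i] + dt * acc5;
      yerr[i] = dt * (acc5 - acc4);
      double sc = (i < 2 ? atolV : atolG) +
                  rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > err) err = e;
      if (!std::isfinite(ynew[i])) err = 1e10;  // reject and shrink the step
    }

    if (err <= 1.0) {  // accept
      double told = t, vold = y[0];
      t += dt;
      for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
      for (int g = 0; g < NGATE; ++g) {
        if (y[2 + g] < 0.0) y[2 + g] = 0.0;
        if (y[2 + g] > 1.0) y[2 + g] = 1.0;
      }
      if (vold < 0.0 && y[0] >= 0.0) {
        double tc = told + dt * (0.0 - vold) / (y[0] - vold);
        if (tc >= watch_from && tc <= watch_to) crossings.push_back(tc);
      }
      if (t >= watch_from && t <= watch_to && y[0] > vmax) vmax = y[0];
      if (record) {
        traj.push_back(t);
        for (int i = 0; i < NSTATE; ++i) traj.push_back(y[i]);
      }
      ++nstep;
      while (seg < nseg && stim_t[seg] <= t + 1e-12) ++seg;
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      if (fac > 5.0) fac = 5.0;
      dt *= fac;
    } else {  // reject
      ++nreject;
      double fac = 0.9 * std::pow(err, -0.2);
      if (fac < 0.2) fac = 0.2;
      dt *= fac;
      if (dt < 1e-10)
        stop("step size underflow at t = %g ms (stiffness or invalid "
             "parameters)", t);
    }
  }

  List out = List::create(
      _["state"] = NumericVector(y, y + NSTATE),
      _["crossings"] = wrap(crossings), _["vmax"] = vmax,
      _["n_steps"] = (double)nstep, _["n_rejected"] = (double)nreject);
  if (record) {
    const int nrow = traj.size() / (NSTATE + 1);
    NumericMatrix tm(nrow, NSTATE + 1);
    for (int r = 0; r < nrow; ++r)
      for (int c = 0; c <= NSTATE; ++c) tm(r, c) = traj[r * (NSTATE + 1) + c];
    out["trajectory"] = tm;
  }
  return out;
}
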