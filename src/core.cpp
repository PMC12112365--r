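// Closed-loop lumped-parameter circulation: 4 time-varying elastance
// chambers, aortic Windkessel + 5 parallel systemic compartments, venous
// pool, lumped pulmonary arterial/venous pair.  Fixed-step classical RK4;
// the system is non-stiff (linear resistances, smooth elastances, ideal
// diode valves) so a small fixed step is both simpler and reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layout (volumes, mL):
// 0 V_LV, 1 V_LA, 2 V_RV, 3 V_RA, 4 V_Ao, 5..9 V_s1..V_s5,
// 10 V_ven, 11 V_PA, 12 V_PU; state 13 is the aortic valve flow Q_av
// (mL/s): the aortic valve carries an inertance so ejection has momentum
// and late-systolic aortic pressure falls below peak systolic pressure.
static const int N_STATE = 14;
static const int N_VOL = 13;  // states 0..12 are volumes

struct Chamber {
  double Emax, Emin, V0;
  double onset;   // activation onset within pacing cycle (s)
  double tau1, tau2, m1, m2;
  double cutoff;  // activation identically 0 for x >= cutoff
  double anorm;   // max of the un-normalised double-Hill shape
};

struct Pars {
  double period;
  Chamber ch[4];              // LV, LA, RV, RA
  double C_A, Vun_Ao;
  double C_s[5], Vun_s[5], R_up[5], R_dn[5];
  double C_ven, Vun_ven, R_ven;
  double C_PA, Vun_PA, R_pul, C_PU, Vun_PU, R_pula;
  double R_mv, R_av, R_tv, R_pav, L_av;
  bool vco;
  double vco_t_start, vco_ramp, vco_maxf;
};

static inline double act_shape(double x, const Chamber &c) {
  if (x < 0.0 || x >= c.cutoff) return 0.0;
  double g1 = std::pow(x / c.tau1, c.m1);
  g1 = g1 / (1.0 + g1);
  double g2 = 1.0 / (1.0 + std::pow(x / c.tau2, c.m2));
  double a = g1 * g2 / c.anorm;
  return (a < 1e-12) ? 0.0 : a;
}

static inline double elastance(double t_cycle, const Chamber &c, double period) {
  double x = t_cycle - c.onset;
  if (x < 0.0) x += period;
  return c.Emin + (c.Emax - c.Emin) * act_shape(x, c);
}

static inline double vco_factor(double t, const Pars &p) {
  if (!p.vco || t <= p.vco_t_start) return 1.0;
  double u = (t - p.vco_t_start) / p.vco_ramp;
  if (u >= 1.0) u = 1.0;
  return 1.0 + (p.vco_maxf - 1.0) * u;
}

static inline double pos(double x) { return x > 0.0 ? x : 0.0; }

// dy/dt; also fills pressures/flows if out != NULL
static void rhs(double t, const double *y, double *dy, const Pars &p,
                double *P = 0, double *Q_av_out = 0) {
  double tc = std::fmod(t, p.period);
  double P_LV = elastance(tc, p.ch[0], p.period) * (y[0] - p.ch[0].V0);
  double P_LA = elastance(tc, p.ch[1], p.period) * (y[1] - p.ch[1].V0);
  double P_RV = elastance(tc, p.ch[2], p.period) * (y[2] - p.ch[2].V0);
  double P_RA = elastance(tc, p.ch[3], p.period) * (y[3] - p.ch[3].V0);
  double P_Ao = (y[4] - p.Vun_Ao) / p.C_A;
  double P_s[5];
  for (int i = 0; i < 5; ++i) P_s[i] = (y[5 + i] - p.Vun_s[i]) / p.C_s[i];
  double P_ven = (y[10] - p.Vun_ven) / p.C_ven;
  double P_PA = (y[11] - p.Vun_PA) / p.C_PA;
  double P_PU = (y[12] - p.Vun_PU) / p.C_PU;

  double Q_mv = pos((P_LA - P_LV) / p.R_mv);
  // aortic valve: diode in series with resistance and inertance
  double Q_av = pos(y[13]);
  double dQ_av;
  if (y[13] > 0.0 || P_LV > P_Ao)
    dQ_av = (P_LV - P_Ao - p.R_av * Q_av) / p.L_av;
  else
    dQ_av = -200.0 * y[13];  // valve shut: relax any negative flow to 0
  double Q_tv = pos((P_RA - P_RV) / p.R_tv);
  double Q_pav = pos((P_RV - P_PA) / p.R_pav);
  double Q_up[5], Q_dn[5], sum_up = 0.0, sum_dn = 0.0;
  for (int i = 0; i < 5; ++i) {
    Q_up[i] = (P_Ao - P_s[i]) / p.R_up[i];
    Q_dn[i] = (P_s[i] - P_ven) / p.R_dn[i];
    sum_up += Q_up[i];
    sum_dn += Q_dn[i];
  }
  double Q_vr = (P_ven - P_RA) / (p.R_ven * vco_factor(t, p));
  double Q_pul = (P_PA - P_PU) / p.R_pul;
  double Q_pula = (P_PU - P_LA) / p.R_pula;

  dy[0] = Q_mv - Q_av;          // LV
  dy[1] = Q_pula - Q_mv;        // LA
  dy[2] = Q_tv - Q_pav;         // RV
  dy[3] = Q_vr - Q_tv;          // RA
  dy[4] = Q_av - sum_up;        // aorta
  for (int i = 0; i < 5; ++i) dy[5 + i] = Q_up[i] - Q_dn[i];
  dy[10] = sum_dn - Q_vr;       // venous pool
  dy[11] = Q_pav - Q_pul;       // pulmonary artery
  dy[12] = Q_pul - Q_pula;      // pulmonary veins
  dy[13] = dQ_av;               // aortic valve flow

  if (P) {
    P[0] = P_LV; P[1] = P_LA; P[2] = P_RV; P[3] = P_RA;
    P[4] = P_Ao; for (int i = 0; i < 5; ++i) P[5 + i] = P_s[i];
    P[10] = P_ven; P[11] = P_PA; P[12] = P_PU;
  }
  if (Q_av_out) *Q_av_out = Q_av;
}

static Chamber chamber_from_row(const NumericMatrix &m, int r) {
  Chamber c;
  c.Emax = m(r, 0); c.Emin = m(r, 1); c.V0 = m(r, 2); c.onset = m(r, 3);
  c.tau1 = m(r, 4); c.tau2 = m(r, 5); c.m1 = m(r, 6); c.m2 = m(r, 7);
  c.cutoff = m(r, 8); c.anorm = m(r, 9);
  return c;
}

static Pars unpack(const List &pars) {
  Pars p;
  p.period = as<double>(pars["period"]);
  NumericMatrix ch = pars["chambers"];  // rows LV, LA, RV, RA; 10 cols
  for (int r = 0; r < 4; ++r) p.ch[r] = chamber_from_row(ch, r);
  p.C_A = as<double>(pars["C_A"]);   p.Vun_Ao = as<double>(pars["Vun_Ao"]);
  NumericVector Cs = pars["C_s"], Vs = pars["Vun_s"],
                Ru = pars["R_up"], Rd = pars["R_dn"];
  for (int i = 0; i < 5; ++i) {
    p.C_s[i] = Cs[i]; p.Vun_s[i] = Vs[i]; p.R_up[i] = Ru[i]; p.R_dn[i] = Rd[i];
  }
  p.C_ven = as<double>(pars["C_ven"]); p.Vun_ven = as<double>(pars["Vun_ven"]);
  p.R_ven = as<double>(pars["R_ven"]);
  p.C_PA = as<double>(pars["C_PA"]);   p.Vun_PA = as<double>(pars["Vun_PA"]);
  p.R_pul = as<double>(pars["R_pul"]);
  p.C_PU = as<double>(pars["C_PU"]);   p.Vun_PU = as<double>(pars["Vun_PU"]);
  p.R_pula = as<double>(pars["R_pula"]);
  p.R_mv = as<double>(pars["R_mv"]); p.R_av = as<double>(pars["R_av"]);
  p.R_tv = as<double>(pars["R_tv"]); p.R_pav = as<double>(pars["R_pav"]);
  p.L_av = as<double>(pars["L_av"]);
  p.vco = as<bool>(pars["vco"]);
  if (p.vco) {
    p.vco_t_start = as<double>(pars["vco_t_start"]);
    p.vco_ramp = as<double>(pars["vco_ramp"]);
    p.vco_maxf = as<double>(pars["vco_maxf"]);
  } else {
    p.vco_t_start = 0.0; p.vco_ramp = 1.0; p.vco_maxf = 1.0;
  }
  return p;
}

// [[Rcpp::export]]
NumericVector cv_derivs_cpp(List pars, NumericVector y, double t) {
  Pars p = unpack(pars);
  if (y.size() != N_STATE) stop("state vector must have length %d", N_STATE);
  double dy[N_STATE];
  rhs(t, y.begin(), dy, p);
  NumericVector out(N_STATE);
  for (int i = 0; i < N_STATE; ++i) out[i] = dy[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cv_elastance_cpp(NumericVector t_cycle, double period,
                               NumericVector chamber_row) {
  NumericMatrix m(1, 10);
  for (int j = 0; j < 10; ++j) m(0, j) = chamber_row[j];
  Chamber c = chamber_from_row(m, 0);
  NumericVector out(t_cycle.size());
  for (int i = 0; i < t_cycle.size(); ++i)
    out[i] = elastance(t_cycle[i], c, period);
  return out;
}

// [[Rcpp::export]]
List cv_simulate_cpp(List pars, NumericVector y0, double duration,
                     double dt, double dt_out, double t_record) {
  Pars p = unpack(pars);
  if (y0.size() != N_STATE) stop("initial state must have length %d", N_STATE);
  double y[N_STATE], k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE],
         tmp[N_STATE];
  for (int i = 0; i < N_STATE; ++i) y[i] = y0[i];

  long n_steps = (long)std::llround(duration / dt);
  int thin = (int)std::llround(dt_out / dt);
  if (thin < 1) thin = 1;
  long first_rec = (long)std::llround(t_record / dt);
  long n_out = 0;
  for (long s = 0; s <= n_steps; ++s)
    if (s >= first_rec && s % thin == 0) ++n_out;

  NumericVector t_out(n_out);
  NumericMatrix P_out(n_out, N_VOL), V_out(n_out, N_VOL);
  NumericVector Qav_out(n_out);

  long row = 0;
  double t = 0.0;
  for (long s = 0; s <= n_steps; ++s) {
    t = s * dt;
    if (s >= first_rec && s % thin == 0) {
      double Pn[N_VOL], Qav;
      double dy[N_STATE];
      rhs(t, y, dy, p, Pn, &Qav);
      t_out[row] = t;
      for (int i = 0; i < N_VOL; ++i) {
        P_out(row, i) = Pn[i];
        V_out(row, i) = y[i];
      }
      Qav_out[row] = Qav;
      ++row;
    }
    if (s == n_steps) break;
    rhs(t, y, k1, p);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    rhs(t + 0.5 * dt, tmp, k2, p);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    rhs(t + 0.5 * dt, tmp, k3, p);
    for (int i = 0; i < N_STATE; ++i) tmp[i] = y[i] + dt * k3[i];
    rhs(t + dt, tmp, k4, p);
    for (int i = 0; i < N_STATE; ++i) {
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(y[i]))
        stop("numerical failure: non-finite state %d at t = %.4f s",
             i + 1, t + dt);
      if (i < N_VOL && y[i] < -1e-6)
        stop("numerical failure: negative volume in state %d at t = %.4f s",
             i + 1, t + dt);
    }
  }
  return List::create(_["t"] = t_out, _["P"] = P_out, _["V"] = V_out,
                      _["Q_av"] = Qav_out);
}

// Isolated 2-element Windkessel discharging through its resistance, run
// with the same RK4 stepper: oracle for the integrator (analytic RC decay).
// [[Rcpp::export]]
NumericVector rc_decay_cpp(double P0, double R, double C, double duration,
                           double dt, double dt_out) {
  double V = P0 * C;
  long n_steps = (long)std::llround(duration / dt);
  int thin = (int)std::llround(dt_out / dt);
  if (thin < 1) thin = 1;
  long n_out = n_steps / thin + 1;
  NumericVector out(n_out);
  long row = 0;
  for (long s = 0; s <= n_steps; ++s) {
    if (s % thin == 0) out[row++] = V / C;
    if (s == n_steps) break;
    double k1 = -V / (R * C);
    double k2 = -(V + 0.5 * dt * k1) / (R * C);
    double k3 = -(V + 0.5 * dt * k2) / (R * C);
    double k4 = -(V + dt * k3) / (R * C);
    V += dt / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
  }
  return out;
}
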