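// Hybrid event-driven simulator for the bipedal trunk-SLIP walker.
//
// Continuous state (10): x, y, vx, vy, phi, phidot, A_RF1, A_HAM1, A_RF2, A_HAM2.
// Discrete state: per-leg stance flag + stance-foot x position, reflex-force
// delay buffers, takeoff arming and mid-stance pending flags.
//
// Integrator: adaptive Dormand-Prince 5(4) with cubic Hermite dense output.
// Events (touchdown, takeoff, mid-stance crossing, falls) are localized by
// bisection on the dense output.  The step size is capped at the reflex delay
// so delayed leg forces are always interpolated inside the recorded history.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const int NS = 10;

struct Pars {
  // trunk and leg mechanics
  double m, J, rh, l0, g, k, mu, vbla_g;
  // Hill-type muscle constants
  double Fmax, lopt, vmax, w, c, Ne, kappa, rho, r0;
  double Lrf0, Lham0, phiref_rf, phiref_ham;
  // reflex
  double stim0, delta_p, Tecc, stim_lo, stim_hi;
  // numerics
  double rtol, atol, hmax, hmin, refractory;
  // fall thresholds
  double fall_yh, fall_tilt;
};

enum CtrlType { CT_PASSIVE = 0, CT_FMCH = 1, CT_NMF = 2, CT_PREFLEX = 3, CT_ADAPTIVE = 4 };

struct Ctrl {
  int type;
  double G_fmch, phi_h0;
  // reflex gains currently in force (shared by both legs)
  double g_ham, g_rf;
  // preflex activation library: time since leg touchdown -> (A_RF, A_HAM)
  std::vector<double> pf_t, pf_arf, pf_aham;
  // adaptive layer
  double K[10];       // 2x5 row-major: row 0 -> G_HAM, row 1 -> G_RF
  double Sstar[5], Ustar[2];
  bool adapt;
};

struct LegState {
  bool stance;
  double foot_x;
  bool armed;       // takeoff event armed once the leg has been loaded
  bool ms_pending;  // mid-stance crossing not yet fired for this stance period
  double last_td;   // time of last touchdown (for preflex replay)
};

struct Hist {  // per-leg axial leg-force history for the reflex delay
  // C1 cubic-Hermite record (value + time derivative at each accepted step)
  // so the delayed force does not inject derivative kinks into the ODE
  std::vector<double> t, f, fd;
  double interp(double tq) const {
    if (t.empty()) return 0.0;
    if (tq <= t.front()) return f.front();
    if (tq >= t.back()) return f.back();
    size_t i = t.size() - 1;
    while (i > 0 && t[i - 1] > tq) --i;
    const double t0 = t[i - 1], t1 = t[i];
    if (t1 <= t0) return f[i];
    const double h = t1 - t0, th = (tq - t0) / h, t2 = th * th;
    const double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
    const double h10 = th * (1 - th) * (1 - th);
    const double h01 = t2 * (3 - 2 * th);
    const double h11 = t2 * (th - 1);
    double v = h00 * f[i - 1] + h * h10 * fd[i - 1] + h01 * f[i] + h * h11 * fd[i];
    return v < 0.0 ? 0.0 : v;
  }
  void push(double tt, double ff, double ffd) {
    if (!t.empty() && tt <= t.back()) return;
    t.push_back(tt); f.push_back(ff); fd.push_back(ffd);
  }
};

struct LegDiag {
  bool stance;
  double foot_x, l, fs, fsd, fx, fy, tau, phih, phidoth, arf_u, aham_u;
};

struct Deriv {
  double dy[NS];
  LegDiag leg[2];
};

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline double fl_curve(double L, const Pars& p) {
  double z = std::fabs((L - p.lopt) / (p.lopt * p.w));
  return std::exp(p.c * z * z * z);
}

static inline double fv_curve(double v, const Pars& p) {
  // v in lopt/s, lengthening positive; p.vmax < 0 (shortening convention)
  if (v < 0.0) {
    if (v <= p.vmax) return 0.0;  // shortening faster than v_max
    return (p.vmax - v) / (p.vmax + p.kappa * v);
  }
  return p.Ne + (p.Ne - 1.0) * (p.vmax + v) / (7.56 * p.kappa * v - p.vmax);
}

static inline double pf_lookup(const std::vector<double>& tg,
                               const std::vector<double>& vg, double tq) {
  if (tg.empty()) return 0.0;
  if (tq <= tg.front()) return vg.front();
  if (tq >= tg.back()) return vg.back();  // hold last value beyond the record
  size_t lo = 0, hi = tg.size() - 1;
  while (hi - lo > 1) { size_t mid = (lo + hi) / 2; if (tg[mid] <= tq) lo = mid; else hi = mid; }
  double a = (tq - tg[lo]) / (tg[hi] - tg[lo]);
  return (1.0 - a) * vg[lo] + a * vg[hi];
}

class Walker {
public:
  Pars p;
  Ctrl c;
  LegState leg[2];
  Hist hist[2];
  double t;
  double y[NS];

  // bookkeeping
  int n_td, n_to, n_ms;
  bool fell;
  std::string status, reason;
  double t_perturb;

  // perturbation spec
  int pert_kind;       // 0 none, 1 set_phidot, 2 add_phidot, 3 set_phi
  double pert_mag;
  int pert_td_index;   // fire at this touchdown count
  bool pert_done;

  double t_last_event;

  // times at which the delayed reflex force is non-smooth (event time + delay);
  // integration steps are aligned on these so the ODE stays smooth within steps
  std::vector<double> brk;
  size_t brk_i;

  // records
  std::vector<double> ev_t; std::vector<int> ev_kind, ev_leg;
  std::vector<double> step_t, step_x; std::vector<int> step_leg;
  std::vector<double> poin;  // rows of 9: t, leg, S(5), g_ham, g_rf
  std::vector<double> traj;  // rows of 31
  bool record;
  long max_traj_rows;

  Walker() : t(0), n_td(0), n_to(0), n_ms(0), fell(false), status("running"),
             t_perturb(NA_REAL), pert_kind(0), pert_mag(0), pert_td_index(-1),
             pert_done(false), t_last_event(-1e30), brk_i(0), record(false),
             max_traj_rows(4000000) {}

  void rhs(double tt, const double* yy, Deriv& d) const {
    const double x = yy[0], yc = yy[1], vx = yy[2], vy = yy[3];
    const double phi = yy[4], phidot = yy[5];
    const double xh = x - p.rh * std::cos(phi);
    const double yh = yc - p.rh * std::sin(phi);
    const double xhd = vx + p.rh * std::sin(phi) * phidot;
    const double yhd = vy - p.rh * std::cos(phi) * phidot;

    double sfx = 0.0, sfy = 0.0, stau = 0.0;

    for (int i = 0; i < 2; ++i) {
      LegDiag& L = d.leg[i];
      L.stance = leg[i].stance;
      L.foot_x = leg[i].foot_x;
      L.l = NA_REAL; L.fs = 0; L.fsd = 0; L.fx = 0; L.fy = 0; L.tau = 0;
      L.phih = NA_REAL; L.phidoth = NA_REAL;
      L.arf_u = NA_REAL; L.aham_u = NA_REAL;
      if (!leg[i].stance) continue;

      const double dx = xh - leg[i].foot_x;
      const double l = std::sqrt(dx * dx + yh * yh);
      const double ll = (l > 1e-12) ? l : 1e-12;
      const double ldot = (dx * xhd + yh * yhd) / ((l > 1e-12) ? l : 1e-12);
      double fs = p.k * (p.l0 - l), fsd = -p.k * ldot;
      if (fs < 0.0) { fs = 0.0; fsd = 0.0; }  // the leg spring cannot pull
      // hip angle between trunk axis and hip->foot leg axis (~pi upright);
      // increases as the leg moves backward relative to the trunk, so the
      // HAM muscle shortens with increasing phi_h (Hill-pair convention)
      const double phih = phi + std::atan2(yh, -dx);
      const double phidoth = phidot + (yh * xhd - yhd * dx) / (ll * ll);

      double tau = 0.0, arf_u = NA_REAL, aham_u = NA_REAL;
      if (c.type == CT_FMCH) {
        tau = c.G_fmch * fs * (c.phi_h0 - phih);
      } else if (c.type == CT_NMF || c.type == CT_ADAPTIVE || c.type == CT_PREFLEX) {
        double A_rf, A_ham;
        if (c.type == CT_PREFLEX) {
          const double ts = tt - leg[i].last_td;
          A_rf = pf_lookup(c.pf_t, c.pf_arf, ts);
          A_ham = pf_lookup(c.pf_t, c.pf_aham, ts);
        } else {
          A_rf = yy[6 + 2 * i];
          A_ham = yy[7 + 2 * i];
        }
        const double Lrf = p.Lrf0 + p.rho * p.r0 * (phih - p.phiref_rf);
        const double Lham = p.Lham0 + p.rho * p.r0 * (p.phiref_ham - phih);
        const double vrf = p.rho * p.r0 * phidoth / p.lopt;
        const double vham = -p.rho * p.r0 * phidoth / p.lopt;
        const double Frf = A_rf * p.Fmax * fl_curve(Lrf, p) * fv_curve(vrf, p);
        const double Fham = A_ham * p.Fmax * fl_curve(Lham, p) * fv_curve(vham, p);
        tau = (Fham - Frf) * p.r0;
        arf_u = A_rf; aham_u = A_ham;
      }

      const double fx = fs * dx / ll + tau * yh / (ll * ll);
      const double fy = fs * yh / ll - tau * dx / (ll * ll);
      sfx += fx; sfy += fy; stau += tau;

      L.l = l; L.fs = fs; L.fsd = fsd; L.fx = fx; L.fy = fy; L.tau = tau;
      L.phih = phih; L.phidoth = phidoth; L.arf_u = arf_u; L.aham_u = aham_u;
    }

    d.dy[0] = vx;
    d.dy[1] = vy;
    d.dy[2] = sfx / p.m;
    d.dy[3] = sfy / p.m - p.g;
    d.dy[4] = phidot;
    d.dy[5] = (stau + p.rh * (sfx * std::sin(phi) - sfy * std::cos(phi))) / p.J;

    // excitation-contraction coupling (first-order lag to saturated STIM)
    for (int i = 0; i < 2; ++i) {
      double fdel = hist[i].interp(tt - p.delta_p);
      if (fdel < 0.0) fdel = 0.0;
      const double s_rf = clampd(p.stim0 + c.g_rf * fdel, p.stim_lo, p.stim_hi);
      const double s_ham = clampd(p.stim0 + c.g_ham * fdel, p.stim_lo, p.stim_hi);
      d.dy[6 + 2 * i] = (s_rf - yy[6 + 2 * i]) / p.Tecc;
      d.dy[7 + 2 * i] = (s_ham - yy[7 + 2 * i]) / p.Tecc;
    }
  }

  // ---- event functions -----------------------------------------------------
  // All events fire on a (+ -> <=0) crossing of a continuous scalar.

  // touchdown of the swing leg while leg `s` is the single stance leg: the
  // swing foot (hip + l0 * VBLA unit direction) reaches the ground.  A short
  // refractory after the last event prevents rebound chatter at takeoff.
  double g_touchdown(double tt, const double* yy, int s) const {
    (void)s;
    const double vx = yy[2], vy = yy[3], phi = yy[4];
    const double yh = yy[1] - p.rh * std::sin(phi);
    const double ox = (1.0 - p.mu) * vx;
    const double oy = (1.0 - p.mu) * vy - p.mu * p.vbla_g;
    const double on = std::sqrt(ox * ox + oy * oy);
    if (on < 1e-12 || oy >= 0.0) return 1.0;  // no downward leg direction
    const double hsw = yh + p.l0 * (oy / on);
    double gv = hsw;
    if (vy > gv) gv = vy;            // armed only while the CoM is descending
    const double refr = (t_last_event + p.refractory) - tt;
    if (refr > gv) gv = refr;        // event refractory
    return gv;
  }

  double vbla_foot_x(const double* yy) const {
    const double vx = yy[2], vy = yy[3], phi = yy[4];
    const double xh = yy[0] - p.rh * std::cos(phi);
    const double ox = (1.0 - p.mu) * vx;
    const double oy = (1.0 - p.mu) * vy - p.mu * p.vbla_g;
    const double on = std::sqrt(ox * ox + oy * oy);
    return xh + p.l0 * (ox / on);
  }

  // ---- integration ---------------------------------------------------------

  void record_traj(double tt, const double* yy, const Deriv& d) {
    if (!record) return;
    if ((long)(traj.size() / 31) >= max_traj_rows) return;
    traj.push_back(tt);
    for (int i = 0; i < NS; ++i) traj.push_back(yy[i]);
    for (int i = 0; i < 2; ++i) {
      const LegDiag& L = d.leg[i];
      traj.push_back(L.stance ? 1.0 : 0.0);
      traj.push_back(L.stance ? L.foot_x : NA_REAL);
      traj.push_back(L.fs); traj.push_back(L.fx); traj.push_back(L.fy);
      traj.push_back(L.tau); traj.push_back(L.phih); traj.push_back(L.phidoth);
      traj.push_back(L.arf_u); traj.push_back(L.aham_u);
    }
  }

  void push_hist(double tt, const Deriv& d) {
    for (int i = 0; i < 2; ++i)
      hist[i].push(tt, leg[i].stance ? d.leg[i].fs : 0.0,
                   leg[i].stance ? d.leg[i].fsd : 0.0);
  }

  void add_event(double tt, int kind, int lg) {
    ev_t.push_back(tt); ev_kind.push_back(kind); ev_leg.push_back(lg);
  }

  // Dormand-Prince 5(4) coefficients
  void dp_step(double tt, const double* y0, const double* f0, double h,
               double* y1, double* f1, double* err, Deriv& dtmp) const {
    static const double
      a21 = 1.0 / 5,
      a31 = 3.0 / 40, a32 = 9.0 / 40,
      a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9,
      a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561, a54 = -212.0 / 729,
      a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247, a64 = 49.0 / 176,
      a65 = -5103.0 / 18656,
      b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192, b5 = -2187.0 / 6784,
      b6 = 11.0 / 84,
      e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920, e5 = -17253.0 / 339200,
      e6 = 22.0 / 525, e7 = -1.0 / 40;
    double k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], yt[NS];
    for (int i = 0; i < NS; ++i) yt[i] = y0[i] + h * a21 * f0[i];
    rhs(tt + h / 5.0, yt, dtmp); for (int i = 0; i < NS; ++i) k2[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i) yt[i] = y0[i] + h * (a31 * f0[i] + a32 * k2[i]);
    rhs(tt + 3.0 * h / 10.0, yt, dtmp); for (int i = 0; i < NS; ++i) k3[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i) yt[i] = y0[i] + h * (a41 * f0[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(tt + 4.0 * h / 5.0, yt, dtmp); for (int i = 0; i < NS; ++i) k4[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i)
      yt[i] = y0[i] + h * (a51 * f0[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(tt + 8.0 * h / 9.0, yt, dtmp); for (int i = 0; i < NS; ++i) k5[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i)
      yt[i] = y0[i] + h * (a61 * f0[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
    rhs(tt + h, yt, dtmp); for (int i = 0; i < NS; ++i) k6[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i)
      y1[i] = y0[i] + h * (b1 * f0[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
    rhs(tt + h, y1, dtmp); for (int i = 0; i < NS; ++i) f1[i] = dtmp.dy[i];
    for (int i = 0; i < NS; ++i)
      err[i] = h * (e1 * f0[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i] + e7 * f1[i]);
  }

  static void hermite(double th, double h, const double* y0, const double* f0,
                      const double* y1, const double* f1, double* out) {
    const double t2 = th * th;
    const double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
    const double h10 = th * (1 - th) * (1 - th);
    const double h01 = t2 * (3 - 2 * th);
    const double h11 = t2 * (th - 1);
    for (int i = 0; i < NS; ++i)
      out[i] = h00 * y0[i] + h * h10 * f0[i] + h01 * y1[i] + h * h11 * f1[i];
  }

  // signed event values at an interpolated time
  struct EvSet { double g[6]; int n; int kind[6]; int lg[6]; };

  void eval_events(double tt, const double* yy, EvSet& es) const {
    es.n = 0;
    const double phi = yy[4];
    const double yh = yy[1] - p.rh * std::sin(phi);
    const double xh = yy[0] - p.rh * std::cos(phi);
    int nst = (leg[0].stance ? 1 : 0) + (leg[1].stance ? 1 : 0);
    Deriv d;
    rhs(tt, yy, d);
    // a stance leg unloads when its vertical GRF vanishes or the spring
    // reaches its rest length (the leg cannot pull on the ground)
    if (nst == 1) {
      const int s = leg[0].stance ? 0 : 1;
      es.g[es.n] = g_touchdown(tt, yy, s); es.kind[es.n] = 1; es.lg[es.n] = 1 - s; es.n++;
      if (leg[s].armed) {
        es.g[es.n] = std::min(d.leg[s].fy, p.k * (p.l0 - d.leg[s].l));
        es.kind[es.n] = 5; es.lg[es.n] = s; es.n++;
      }
      if (leg[s].ms_pending) {
        es.g[es.n] = -(xh - leg[s].foot_x); es.kind[es.n] = 3; es.lg[es.n] = s; es.n++;
      }
    } else if (nst == 2) {
      for (int i = 0; i < 2; ++i) {
        if (leg[i].armed) {
          es.g[es.n] = std::min(d.leg[i].fy, p.k * (p.l0 - d.leg[i].l));
          es.kind[es.n] = 2; es.lg[es.n] = i; es.n++;
        }
        if (leg[i].ms_pending) {
          es.g[es.n] = -(xh - leg[i].foot_x); es.kind[es.n] = 3; es.lg[es.n] = i; es.n++;
        }
      }
    }
    es.g[es.n] = yh - p.fall_yh; es.kind[es.n] = 6; es.lg[es.n] = -1; es.n++;
    es.g[es.n] = p.fall_tilt - std::fabs(phi - M_PI / 2.0); es.kind[es.n] = 7; es.lg[es.n] = -1; es.n++;
  }

  // main loop; stop_td/stop_ms <= 0 means "not a stopping rule"
  void run(double t_max, int stop_td, int stop_ms) {
    double f0[NS], f1[NS], yn[NS], errv[NS], yint[NS];
    Deriv d0, dtmp, dn;
    rhs(t, y, d0);
    for (int i = 0; i < NS; ++i) f0[i] = d0.dy[i];
    push_hist(t, d0);
    record_traj(t, y, d0);
    arm_check(d0);

    double h = std::min(p.hmax, 1e-4);
    long iter = 0, max_iter = 100000000L;

    while (t < t_max) {
      if (++iter > max_iter) { status = "numeric_failure"; reason = "iteration limit"; return; }
      if (h > p.hmax) h = p.hmax;
      if (t + h > t_max) h = t_max - t;
      while (brk_i < brk.size() && brk[brk_i] <= t + p.hmin) ++brk_i;
      bool hit_brk = false;
      if (brk_i < brk.size() && t + h > brk[brk_i]) { h = brk[brk_i] - t; hit_brk = true; }
      if (h < p.hmin) { status = "numeric_failure"; reason = "step underflow"; return; }

      dp_step(t, y, f0, h, yn, f1, errv, dtmp);
      double errn = 0.0;
      bool bad = false;
      for (int i = 0; i < NS; ++i) {
        if (!std::isfinite(yn[i])) { bad = true; break; }
        const double sc = p.atol + p.rtol * std::max(std::fabs(y[i]), std::fabs(yn[i]));
        const double e = errv[i] / sc;
        errn += e * e;
      }
      errn = std::sqrt(errn / NS);
      if (bad || errn > 1.0) {
        const double fac = bad ? 0.2 : std::max(0.2, 0.9 * std::pow(errn, -0.2));
        h *= fac;
        continue;
      }

      // accepted: look for events in [t, t+h]
      EvSet e0, e1s;
      eval_events(t, y, e0);
      eval_events(t + h, yn, e1s);
      double te_best = -1.0; int kb = 0, lb = -1;
      for (int j = 0; j < e0.n; ++j) {
        // event sets at both ends share layout only if discrete flags are
        // unchanged within the step (they are: flags change only at events)
        if (j >= e1s.n || e0.kind[j] != e1s.kind[j] || e0.lg[j] != e1s.lg[j]) continue;
        if (e0.g[j] > 0.0 && e1s.g[j] <= 0.0) {
          double lo = 0.0, hi = 1.0;
          for (int it2 = 0; it2 < 80; ++it2) {
            const double mid = 0.5 * (lo + hi);
            hermite(mid, h, y, f0, yn, f1, yint);
            EvSet em;
            eval_events(t + mid * h, yint, em);
            double gm = 1.0;
            for (int q = 0; q < em.n; ++q)
              if (em.kind[q] == e0.kind[j] && em.lg[q] == e0.lg[j]) gm = em.g[q];
            if (gm > 0.0) lo = mid; else hi = mid;
          }
          const double te = t + hi * h;
          if (te_best < 0.0 || te < te_best) { te_best = te; kb = e0.kind[j]; lb = e0.lg[j]; }
        }
      }

      if (te_best >= 0.0) {
        const double th = (te_best - t) / h;
        hermite(th, h, y, f0, yn, f1, yint);
        t = te_best;
        for (int i = 0; i < NS; ++i) y[i] = yint[i];
        rhs(t, y, dn);
        push_hist(t, dn);
        record_traj(t, y, dn);
        handle_event(kb, lb);
        if (fell || status != "running") return;
        if (stop_td > 0 && n_td >= stop_td) { status = "completed"; return; }
        if (stop_ms > 0 && n_ms >= stop_ms) { status = "completed"; return; }
        rhs(t, y, d0);
        for (int i = 0; i < NS; ++i) f0[i] = d0.dy[i];
        arm_check(d0);
        h = std::min(h, p.hmax);
        continue;
      }

      // no event: commit the full step
      t += h;
      if (hit_brk && brk_i < brk.size() && t >= brk[brk_i] - p.hmin) ++brk_i;
      for (int i = 0; i < NS; ++i) { y[i] = yn[i]; f0[i] = f1[i]; }
      rhs(t, y, dn);  // cheap relative to the step; refresh diagnostics
      push_hist(t, dn);
      record_traj(t, y, dn);
      arm_check(dn);
      const double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(std::max(errn, 1e-10), -0.2)));
      h *= fac;
    }
    status = "timeout";
  }

  void arm_check(const Deriv& d) {
    for (int i = 0; i < 2; ++i)
      if (leg[i].stance && !leg[i].armed && d.leg[i].fy > 1.0) leg[i].armed = true;
  }

  void handle_event(int kind, int lg) {
    t_last_event = t;
    if (p.delta_p > 0.0) brk.push_back(t + p.delta_p);
    add_event(t, kind, lg);
    const double phi = y[4];
    const double xh = y[0] - p.rh * std::cos(phi);
    const double yh = y[1] - p.rh * std::sin(phi);
    switch (kind) {
      case 1: {  // touchdown of swing leg lg
        leg[lg].stance = true;
        leg[lg].foot_x = vbla_foot_x(y);
        leg[lg].armed = false;
        leg[lg].ms_pending = true;
        leg[lg].last_td = t;
        n_td++;
        step_t.push_back(t); step_x.push_back(y[0]); step_leg.push_back(lg);
        if (pert_kind != 0 && !pert_done && n_td == pert_td_index) {
          if (pert_kind == 1) y[5] = pert_mag;
          else if (pert_kind == 2) y[5] += pert_mag;
          else if (pert_kind == 3) y[4] = pert_mag;
          pert_done = true;
          t_perturb = t;
          add_event(t, 8, -1);
        }
        break;
      }
      case 2: {  // takeoff of leg lg in double support
        leg[lg].stance = false;
        leg[lg].ms_pending = false;
        n_to++;
        break;
      }
      case 3: {  // mid-stance crossing of stance leg lg
        leg[lg].ms_pending = false;
        n_ms++;
        poin.push_back(t); poin.push_back((double)lg);
        poin.push_back(y[2]); poin.push_back(y[1]); poin.push_back(y[3]);
        poin.push_back(y[4]); poin.push_back(y[5]);
        if (c.adapt) {
          const double S[5] = {y[2], y[1], y[3], y[4], y[5]};
          double u[2];
          for (int r = 0; r < 2; ++r) {
            double acc = c.Ustar[r];
            for (int q = 0; q < 5; ++q) acc -= c.K[r * 5 + q] * (S[q] - c.Sstar[q]);
            u[r] = acc < 0.0 ? 0.0 : acc;
          }
          c.g_ham = u[0]; c.g_rf = u[1];
        }
        poin.push_back(c.g_ham); poin.push_back(c.g_rf);
        break;
      }
      case 5: {  // stance-leg unloading in single support -> flight -> fall
        leg[lg].stance = false;
        fell = true; status = "fall"; reason = "flight";
        break;
      }
      case 6: { fell = true; status = "fall"; reason = "hip_height"; (void)xh; (void)yh; break; }
      case 7: { fell = true; status = "fall"; reason = "trunk_tilt"; break; }
    }
  }
};

static double getd(const List& L, const char* nm) {
  if (!L.containsElementNamed(nm)) stop("missing parameter '%s'", nm);
  return as<double>(L[nm]);
}

static void fill_pars(Pars& p, const List& pars) {
  p.m = getd(pars, "m"); p.J = getd(pars, "J_trunk"); p.rh = getd(pars, "r_h");
  p.l0 = getd(pars, "l0"); p.g = getd(pars, "g"); p.k = getd(pars, "k");
  p.mu = getd(pars, "mu_vbla");
  p.vbla_g = pars.containsElementNamed("vbla_g") ? as<double>(pars["vbla_g"]) : p.g;
  p.Fmax = getd(pars, "F_max"); p.lopt = getd(pars, "l_opt"); p.vmax = getd(pars, "v_max");
  p.w = getd(pars, "w"); p.c = getd(pars, "c"); p.Ne = getd(pars, "N_ecc");
  p.kappa = getd(pars, "kappa"); p.rho = getd(pars, "rho"); p.r0 = getd(pars, "r0");
  p.Lrf0 = getd(pars, "L_rf0"); p.Lham0 = getd(pars, "L_ham0");
  p.phiref_rf = getd(pars, "phi_ref_rf"); p.phiref_ham = getd(pars, "phi_ref_ham");
  p.stim0 = getd(pars, "stim0"); p.delta_p = getd(pars, "delta_p");
  p.Tecc = getd(pars, "T_ecc");
  p.stim_lo = getd(pars, "stim_lo"); p.stim_hi = getd(pars, "stim_hi");
  p.rtol = getd(pars, "rtol"); p.atol = getd(pars, "atol");
  p.hmax = getd(pars, "hmax"); p.hmin = getd(pars, "hmin");
  p.refractory = getd(pars, "refractory");
  p.fall_yh = getd(pars, "fall_yh"); p.fall_tilt = getd(pars, "fall_tilt");
  // keep delayed reflex queries inside the recorded history
  if (p.delta_p > 0.0 && p.hmax > p.delta_p) p.hmax = p.delta_p;
}

static void fill_ctrl(Ctrl& c, const List& ctrl) {
  const std::string ty = as<std::string>(ctrl["type"]);
  c.G_fmch = 0; c.phi_h0 = 0; c.g_ham = 0; c.g_rf = 0; c.adapt = false;
  if (ty == "passive") c.type = CT_PASSIVE;
  else if (ty == "fmch") {
    c.type = CT_FMCH;
    c.G_fmch = getd(ctrl, "G_fmch"); c.phi_h0 = getd(ctrl, "phi_h0");
  } else if (ty == "nmf" || ty == "adaptive_nmf") {
    c.type = (ty == "nmf") ? CT_NMF : CT_ADAPTIVE;
    c.g_ham = getd(ctrl, "g_ham"); c.g_rf = getd(ctrl, "g_rf");
    if (c.type == CT_ADAPTIVE) {
      c.adapt = true;
      NumericMatrix K = ctrl["K"];
      if (K.nrow() != 2 || K.ncol() != 5) stop("K must be 2 x 5");
      for (int r = 0; r < 2; ++r) for (int q = 0; q < 5; ++q) c.K[r * 5 + q] = K(r, q);
      NumericVector Ss = ctrl["S_star"], Us = ctrl["U_star"];
      for (int q = 0; q < 5; ++q) c.Sstar[q] = Ss[q];
      c.Ustar[0] = Us[0]; c.Ustar[1] = Us[1];
      c.g_ham = c.Ustar[0]; c.g_rf = c.Ustar[1];
    }
  } else if (ty == "preflex") {
    c.type = CT_PREFLEX;
    NumericVector tg = ctrl["pf_time"], ar = ctrl["pf_a_rf"], ah = ctrl["pf_a_ham"];
    c.pf_t.assign(tg.begin(), tg.end());
    c.pf_arf.assign(ar.begin(), ar.end());
    c.pf_aham.assign(ah.begin(), ah.end());
  } else stop("unknown controller type '%s'", ty.c_str());
}

// [[Rcpp::export]]
List cpp_sim(NumericVector y0, LogicalVector stance, NumericVector foot_x,
             NumericVector last_td, List pars, List ctrl, double t0,
             double t_max, int stop_td, int stop_ms, List perturb, bool record) {
  if (y0.size() != NS) stop("state vector must have length 10");
  Walker w;
  fill_pars(w.p, pars);
  fill_ctrl(w.c, ctrl);
  w.t = t0;
  for (int i = 0; i < NS; ++i) w.y[i] = y0[i];
  for (int i = 0; i < 2; ++i) {
    w.leg[i].stance = stance[i];
    w.leg[i].foot_x = foot_x[i];
    w.leg[i].armed = false;
    w.leg[i].last_td = last_td[i];
    // arm the mid-stance crossing only if the hip is still behind the foot
    const double xh = w.y[0] - w.p.rh * std::cos(w.y[4]);
    w.leg[i].ms_pending = stance[i] && (xh - foot_x[i] < -1e-12);
  }
  // seed the reflex-force history with the current axial forces (steady start)
  {
    Deriv d;
    w.rhs(t0, w.y, d);
    for (int i = 0; i < 2; ++i) {
      const double f = w.leg[i].stance ? d.leg[i].fs : 0.0;
      w.hist[i].push(t0 - w.p.delta_p - 1e-9, f, 0.0);
    }
    if (w.p.delta_p > 0.0) w.brk.push_back(t0 + w.p.delta_p);
  }
  w.record = record;
  if (perturb.containsElementNamed("kind")) {
    const std::string pk = as<std::string>(perturb["kind"]);
    if (pk == "set_phidot") w.pert_kind = 1;
    else if (pk == "add_phidot") w.pert_kind = 2;
    else if (pk == "set_phi") w.pert_kind = 3;
    else w.pert_kind = 0;
    if (w.pert_kind != 0) {
      w.pert_mag = getd(perturb, "magnitude");
      w.pert_td_index = as<int>(perturb["touchdown_index"]);
    }
  }

  w.run(t_max, stop_td, stop_ms);
  if (w.status == "running") w.status = "timeout";

  NumericVector yend(NS);
  for (int i = 0; i < NS; ++i) yend[i] = w.y[i];
  LogicalVector st_end(2);
  NumericVector fx_end(2), ltd_end(2);
  for (int i = 0; i < 2; ++i) {
    st_end[i] = w.leg[i].stance; fx_end[i] = w.leg[i].foot_x; ltd_end[i] = w.leg[i].last_td;
  }

  const int ne = w.ev_t.size();
  NumericMatrix events(ne, 3);
  for (int i = 0; i < ne; ++i) {
    events(i, 0) = w.ev_t[i]; events(i, 1) = w.ev_kind[i]; events(i, 2) = w.ev_leg[i];
  }
  const int nst = w.step_t.size();
  NumericMatrix steps(nst, 3);
  for (int i = 0; i < nst; ++i) {
    steps(i, 0) = w.step_t[i]; steps(i, 1) = w.step_x[i]; steps(i, 2) = w.step_leg[i];
  }
  const int np = w.poin.size() / 9;
  NumericMatrix poin(np, 9);
  for (int i = 0; i < np; ++i)
    for (int j = 0; j < 9; ++j) poin(i, j) = w.poin[i * 9 + j];

  const long ntr = w.traj.size() / 31;
  NumericMatrix traj(ntr, 31);
  for (long i = 0; i < ntr; ++i)
    for (int j = 0; j < 31; ++j) traj(i, j) = w.traj[i * 31 + j];

  return List::create(
    _["status"] = w.status, _["reason"] = w.reason,
    _["t_end"] = w.t, _["y_end"] = yend,
    _["stance_end"] = st_end, _["foot_x_end"] = fx_end, _["last_td_end"] = ltd_end,
    _["n_touchdowns"] = w.n_td, _["n_takeoffs"] = w.n_to, _["n_midstance"] = w.n_ms,
    _["t_perturb"] = w.t_perturb,
    _["events"] = events, _["steps"] = steps, _["poincare"] = poin,
    _["trajectory"] = traj,
    _["gains_end"] = NumericVector::create(w.c.g_ham, w.c.g_rf));
}

// Basin-of-attraction sweep: for each (phi, phidot) cell, start at the
// limit-cycle mid-stance state with the two trunk coordinates replaced, and
// check whether the walker survives `n_steps` touchdowns without falling.
// [[Rcpp::export]]
LogicalMatrix cpp_basin(NumericVector S_star, NumericVector phi_grid,
                        NumericVector phidot_grid, List pars, List ctrl,
                        int n_steps, double t_max) {
  const int nr = phi_grid.size(), nc = phidot_grid.size();
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nc; ++j) {
      Walker w;
      fill_pars(w.p, pars);
      fill_ctrl(w.c, ctrl);
      w.t = 0.0;
      const double phi = phi_grid[i], phidot = phidot_grid[j];
      w.y[0] = 0.0; w.y[1] = S_star[1]; w.y[2] = S_star[0]; w.y[3] = S_star[2];
      w.y[4] = phi; w.y[5] = phidot;
      w.leg[0].stance = true;
      w.leg[0].foot_x = w.y[0] - w.p.rh * std::cos(phi);
      w.leg[0].armed = false; w.leg[0].ms_pending = false; w.leg[0].last_td = -0.2;
      w.leg[1].stance = false; w.leg[1].foot_x = NA_REAL;
      w.leg[1].armed = false; w.leg[1].ms_pending = false; w.leg[1].last_td = -0.7;
      Deriv d;
      w.rhs(0.0, w.y, d);
      const double fs0 = w.leg[0].stance ? d.leg[0].fs : 0.0;
      w.hist[0].push(-w.p.delta_p - 1e-9, fs0, 0.0);
      w.hist[1].push(-w.p.delta_p - 1e-9, 0.0, 0.0);
      if (w.p.delta_p > 0.0) w.brk.push_back(w.p.delta_p);
      // quasi-steady activations for the reconstructed state
      {
        double fdel = fs0;
        w.y[6] = clampd(w.p.stim0 + w.c.g_rf * fdel, w.p.stim_lo, w.p.stim_hi);
        w.y[7] = clampd(w.p.stim0 + w.c.g_ham * fdel, w.p.stim_lo, w.p.stim_hi);
        w.y[8] = w.p.stim0; w.y[9] = w.p.stim0;
      }
      w.record = false;
      w.run(t_max, n_steps, -1);
      out(i, j) = (w.status == "completed" && w.n_td >= n_steps);
    }
  }
  return out;
}
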