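// Compiled simulation core: closed-form linear disposition + adaptive
// Dormand-Prince RK45 for the transit-compartment myelosuppression system.
// Concentrations are supplied to the PD ODE analytically, so the integrated
// system is the 5-state chain per marker only (non-stiff; eigenvalues ~ ktr).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct PK {
  int ncmt;
  double CL, V1, Q, V2;
  // derived
  double k;            // 1-cmt elimination rate
  double alpha, beta;  // 2-cmt exponents
  double C1, C2;       // 2-cmt unit-bolus coefficients (x 1/V1)
  double cut;          // time past infusion end after which the
                       // contribution is below ~3e-20 of its peak
};

PK make_pk(const double* p) {
  PK pk;
  pk.ncmt = (int)p[0];
  pk.CL = p[1]; pk.V1 = p[2]; pk.Q = p[3]; pk.V2 = p[4];
  if (pk.CL <= 0.0 || pk.V1 <= 0.0) stop("PK parameters must be positive");
  if (pk.ncmt == 1) {
    pk.k = pk.CL / pk.V1;
    pk.alpha = pk.beta = pk.C1 = pk.C2 = 0.0;
    pk.cut = 45.0 / pk.k;
  } else {
    if (pk.Q <= 0.0 || pk.V2 <= 0.0)
      stop("two-compartment model needs positive Q and Vp");
    double k10 = pk.CL / pk.V1, k12 = pk.Q / pk.V1, k21 = pk.Q / pk.V2;
    double s = k10 + k12 + k21, prod = k10 * k21;
    double disc = std::sqrt(std::max(s * s - 4.0 * prod, 0.0));
    pk.alpha = 0.5 * (s + disc);
    pk.beta  = 0.5 * (s - disc);
    pk.C1 = (pk.alpha - k21) / (pk.alpha - pk.beta);
    pk.C2 = (k21 - pk.beta) / (pk.alpha - pk.beta);
    pk.k = 0.0;
    pk.cut = 45.0 / pk.beta;
  }
  return pk;
}

// single-infusion unit response at time-since-start tau, infusion length dur,
// rate R (amount/h); returns concentration (amount/V1 units)
inline double conc_one(const PK& pk, double tau, double dur, double R) {
  if (tau <= 0.0 || R == 0.0) return 0.0;
  if (pk.ncmt == 1) {
    if (tau <= dur)
      return R / pk.CL * (1.0 - std::exp(-pk.k * tau));
    double tp = tau - dur;
    return R / pk.CL * (1.0 - std::exp(-pk.k * dur)) * std::exp(-pk.k * tp);
  }
  double a = pk.alpha, b = pk.beta;
  if (tau <= dur) {
    return R / pk.V1 * (pk.C1 * (1.0 - std::exp(-a * tau)) / a +
                        pk.C2 * (1.0 - std::exp(-b * tau)) / b);
  }
  double tp = tau - dur;
  return R / pk.V1 * (pk.C1 * (1.0 - std::exp(-a * dur)) * std::exp(-a * tp) / a +
                      pk.C2 * (1.0 - std::exp(-b * dur)) * std::exp(-b * tp) / b);
}

// superposition over all infusion events; ev rows: (start, duration, rate),
// sorted by start time. Events not yet started or decayed past the
// relevance horizon are skipped.
inline double conc_at(double t, const PK& pk, const NumericMatrix& ev) {
  double c = 0.0;
  for (int i = 0; i < ev.nrow(); ++i) {
    double tau = t - ev(i, 0);
    if (tau <= 0.0) break;  // later events have not started either
    if (tau - ev(i, 1) > pk.cut) continue;
    c += conc_one(pk, tau, ev(i, 1), ev(i, 2));
  }
  return c;
}

// PD right-hand side, nm markers x 5 transit states; pd is nm x 6 laid out
// per marker as (ktr, slope, base, gamma, imp, imk)
inline bool rhs(double t, const double* y, double* dy, const PK& pk,
                const NumericMatrix& ev, const double* pd, int nm) {
  double C = conc_at(t, pk, ev);
  for (int m = 0; m < nm; ++m) {
    const double* p = pd + 6 * m;
    const double ktr = p[0], slope = p[1], base = p[2], gamma = p[3],
                 imp = p[4], imk = p[5];
    const double* a = y + 5 * m;
    double* da = dy + 5 * m;
    double A5 = a[4];
    if (!(A5 > 0.0)) return false;  // surfaced to the step controller
    double B = base + (imp > 0.0 ? imp * (1.0 - std::exp(-imk * t)) : 0.0);
    double fb = (gamma == 0.0) ? 1.0 : std::pow(B / A5, gamma);
    da[0] = ktr * a[0] * ((1.0 - slope * C) * fb - 1.0);
    da[1] = ktr * (a[0] - a[1]);
    da[2] = ktr * (a[1] - a[2]);
    da[3] = ktr * (a[2] - a[3]);
    da[4] = ktr * (a[3] - a[4]);
  }
  return true;
}

// Dormand-Prince 5(4) tableau
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
             e4 = 125.0 / 192 - 393.0 / 640, e5 = -2187.0 / 6784 + 92097.0 / 339200,
             e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

struct Integrator {
  const PK& pk;
  const NumericMatrix& ev;
  const double* pd;
  int nm, n;
  double rtol, atol;
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, ytmp;

  Integrator(const PK& pk_, const NumericMatrix& ev_, const double* pd_,
             int nm_, double rtol_, double atol_)
      : pk(pk_), ev(ev_), pd(pd_), nm(nm_), n(5 * nm_), rtol(rtol_),
        atol(atol_), k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n) {}

  double fail_time;  // last good time when advance() returns false

  // Advance y from t0 exactly to t1 (t1 > t0); false on failure.
  // When output times are supplied (sorted, within (t0, t1]), states are
  // written by cubic Hermite interpolation on the accepted steps into the
  // row-major buffer `out` (n values per output), advancing `oix`.
  bool advance(std::vector<double>& y, double t0, double t1,
               const double* ot = 0, int n_ot = 0, double* out = 0,
               int* oix = 0) {
    double t = t0;
    double h = std::min(1.0, t1 - t0);
    fail_time = t0;
    if (!rhs(t, y.data(), k1.data(), pk, ev, pd, nm)) return false;
    int nstep = 0;
    while (t < t1) {
      if (++nstep > 1000000) { fail_time = t; return false; }
      bool clamped = false;
      if (t + h >= t1) { h = t1 - t; clamped = true; }
      bool ok = true;
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      ok = ok && rhs(t + c2 * h, ytmp.data(), k2.data(), pk, ev, pd, nm);
      if (ok) {
        for (int i = 0; i < n; ++i)
          ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        ok = rhs(t + c3 * h, ytmp.data(), k3.data(), pk, ev, pd, nm);
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        ok = rhs(t + c4 * h, ytmp.data(), k4.data(), pk, ev, pd, nm);
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
        ok = rhs(t + c5 * h, ytmp.data(), k5.data(), pk, ev, pd, nm);
      }
      if (ok) {
        for (int i = 0; i < n; ++i)
          ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
        ok = rhs(t + h, ytmp.data(), k6.data(), pk, ev, pd, nm);
      }
      double err = 0.0;
      if (ok) {
        for (int i = 0; i < n; ++i)
          ytmp[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
        ok = rhs(t + h, ytmp.data(), k7.data(), pk, ev, pd, nm);
        if (ok) {
          for (int i = 0; i < n; ++i) {
            double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                            e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
            double sc = atol + rtol * std::max(std::fabs(y[i]),
                                               std::fabs(ytmp[i]));
            err += (e / sc) * (e / sc);
          }
          err = std::sqrt(err / n);
          if (!std::isfinite(err)) ok = false;
        }
      }
      if (ok && err <= 1.0) {
        if (ot && oix) {
          // dense output over the accepted step (y at t, ytmp at t+h,
          // slopes k1 and k7)
          while (*oix < n_ot && ot[*oix] <= t + h + 1e-12) {
            double th = (ot[*oix] - t) / h;
            if (th < 0) th = 0; if (th > 1) th = 1;
            double h00 = (1 + 2 * th) * (1 - th) * (1 - th);
            double h10 = th * (1 - th) * (1 - th);
            double h01 = th * th * (3 - 2 * th);
            double h11 = th * th * (th - 1);
            double* row = out + (size_t)(*oix) * n;
            for (int i = 0; i < n; ++i)
              row[i] = h00 * y[i] + h * h10 * k1[i] + h01 * ytmp[i] +
                       h * h11 * k7[i];
            ++*oix;
          }
        }
        t += h;
        std::swap(y, ytmp);
        std::swap(k1, k7);  // FSAL
        double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
        h *= std::min(5.0, std::max(0.2, fac));
        if (clamped && t < t1) h = std::min(h, t1 - t);
      } else {
        h *= ok ? std::max(0.2, 0.9 * std::pow(err, -0.2)) : 0.25;
        if (h < 1e-12) { fail_time = t; return false; }
        // k1 still valid at (t, y)
      }
    }
    return true;
  }
};

std::vector<double> event_breaks(const NumericMatrix& ev, double t0, double t1) {
  std::vector<double> br;
  for (int i = 0; i < ev.nrow(); ++i) {
    double s = ev(i, 0), e = ev(i, 0) + ev(i, 1);
    if (s > t0 && s < t1) br.push_back(s);
    if (e > t0 && e < t1) br.push_back(e);
  }
  std::sort(br.begin(), br.end());
  br.erase(std::unique(br.begin(), br.end()), br.end());
  return br;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_conc(NumericVector times, NumericMatrix events,
                       NumericVector pk_par) {
  PK pk = make_pk(REAL(pk_par));
  NumericVector out(times.size());
  for (int i = 0; i < times.size(); ++i)
    out[i] = conc_at(times[i], pk, events);
  return out;
}

// Simulate nm markers jointly; y0 at times[0]; returns length(times) x 5*nm.
// pd_par: nm x 6 matrix, rows (ktr, slope, base, gamma, imp, imk).
// [[Rcpp::export]]
NumericMatrix cpp_simulate(NumericVector times, NumericMatrix events,
                           NumericVector pk_par, NumericMatrix pd_par,
                           NumericVector y0, double rtol, double atol) {
  PK pk = make_pk(REAL(pk_par));
  int nm = pd_par.nrow();
  if (pd_par.ncol() != 6) stop("pd_par must have 6 columns");
  if (y0.size() != 5 * nm) stop("y0 must have length 5 * n_markers");
  int nt = times.size();
  // row-major copy of pd parameters
  std::vector<double> pd(6 * nm);
  for (int m = 0; m < nm; ++m)
    for (int j = 0; j < 6; ++j) pd[6 * m + j] = pd_par(m, j);
  Integrator ig(pk, events, pd.data(), nm, rtol, atol);
  int n = 5 * nm;
  std::vector<double> y(y0.begin(), y0.end());
  NumericMatrix out(nt, n);
  for (int j = 0; j < n; ++j) out(0, j) = y[j];
  for (int i = 1; i < nt; ++i)
    if (times[i] < times[i - 1]) stop("times must be ascending");
  if (nt > 1 && times[nt - 1] > times[0]) {
    std::vector<double> ot(times.begin() + 1, times.end());
    std::vector<double> buf((size_t)ot.size() * n);
    int oix = 0;
    std::vector<double> br = event_breaks(events, times[0], times[nt - 1]);
    br.push_back(times[nt - 1]);
    double cur = times[0];
    for (double b : br) {
      if (b <= cur) continue;
      if (!ig.advance(y, cur, b, ot.data(), (int)ot.size(), buf.data(),
                      &oix))
        stop("integrator failed (state or step underflow); "
             "last good time %f h", ig.fail_time);
      cur = b;
    }
    for (int i = 1; i < nt; ++i) {
      const double* row = buf.data() + (size_t)(i - 1) * n;
      for (int j = 0; j < n; ++j) out(i, j) = row[j];
    }
  } else if (nt > 1) {
    for (int i = 1; i < nt; ++i)
      for (int j = 0; j < n; ++j) out(i, j) = y[j];
  }
  return out;
}

// Batched nadir search used by the titration simulations.
// par rows: (ncmt, CL, V1, Q, V2, then 6 PD values per marker).
// Each row is simulated from t = 0 (all transit states at BASE) to wend;
// the circulating count A5 is scanned on a dt grid over [wstart, wend],
// earliest-minimum tie-break, then refined by a local quadratic fit.
// Returns n x (2*nm): per marker (t_nadir, nadir).
// [[Rcpp::export]]
NumericMatrix cpp_nadir_batch(NumericMatrix par, NumericMatrix events,
                              double wstart, double wend, double dt,
                              double rtol, double atol) {
  if (wend <= 0.0 || wend < wstart || wstart < 0.0)
    stop("invalid nadir window");
  int nm = (par.ncol() - 5) / 6;
  if (par.ncol() != 5 + 6 * nm || nm < 1) stop("bad parameter layout");
  // output grid: 0 ... wend stepping dt, always including wstart and wend
  std::vector<double> grid;
  for (double t = 0.0; t < wend - 1e-9; t += dt) grid.push_back(t);
  grid.push_back(wend);
  if (wstart > 0.0) {
    grid.push_back(wstart);
    std::sort(grid.begin(), grid.end());
    grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  }
  int nt = grid.size();
  NumericMatrix out(par.nrow(), 2 * nm);
  std::vector<double> traj(nt);
  for (int r = 0; r < par.nrow(); ++r) {
    std::vector<double> prow(par.ncol());
    for (int j = 0; j < par.ncol(); ++j) prow[j] = par(r, j);
    PK pk = make_pk(prow.data());
    std::vector<double> pd(6 * nm);
    for (int j = 0; j < 6 * nm; ++j) pd[j] = prow[5 + j];
    std::vector<double> y(5 * nm);
    for (int m = 0; m < nm; ++m)
      for (int s = 0; s < 5; ++s) y[5 * m + s] = pd[6 * m + 2];  // BASE
    Integrator ig(pk, events, pd.data(), nm, rtol, atol);
    int n = 5 * nm;
    std::vector<std::vector<double> > a5(nm, std::vector<double>(nt));
    for (int m = 0; m < nm; ++m) a5[m][0] = y[5 * m + 4];
    // A replicate whose dynamics collapse (circulating pool driven to the
    // bottom of the positive domain, stalling the integrator) is recorded
    // as a zero nadir: it is a catastrophic-toxicity draw, not a grid error.
    bool failed = false;
    {
      std::vector<double> ot(grid.begin() + 1, grid.end());
      std::vector<double> buf((size_t)ot.size() * n);
      int oix = 0;
      std::vector<double> br = event_breaks(events, grid[0], wend);
      br.push_back(wend);
      double cur = grid[0];
      for (double b : br) {
        if (b <= cur) continue;
        if (!ig.advance(y, cur, b, ot.data(), (int)ot.size(), buf.data(),
                        &oix)) {
          failed = true;
          break;
        }
        cur = b;
      }
      if (!failed)
        for (int i = 1; i < nt; ++i)
          for (int m = 0; m < nm; ++m)
            a5[m][i] = buf[(size_t)(i - 1) * n + 5 * m + 4];
    }
    if (failed) {
      for (int m = 0; m < nm; ++m) {
        out(r, 2 * m) = ig.fail_time;
        out(r, 2 * m + 1) = 0.0;
      }
      continue;
    }
    for (int m = 0; m < nm; ++m) {
      int imin = -1;
      double vmin = R_PosInf;
      for (int i = 0; i < nt; ++i) {
        if (grid[i] < wstart - 1e-9) continue;
        if (a5[m][i] < vmin) { vmin = a5[m][i]; imin = i; }
      }
      double tmin = grid[imin], ymin = vmin;
      if (imin > 0 && imin < nt - 1 && grid[imin - 1] >= wstart - 1e-9) {
        // quadratic through the three bracketing grid points
        double t0 = grid[imin - 1], t1 = grid[imin], t2 = grid[imin + 1];
        double y0 = a5[m][imin - 1], y1 = a5[m][imin], y2 = a5[m][imin + 1];
        double d1 = (y1 - y0) / (t1 - t0), d2 = (y2 - y1) / (t2 - t1);
        double c2n = (d2 - d1) / (t2 - t0);  // Newton divided difference
        if (c2n > 0.0) {
          double tv = 0.5 * (t0 + t1) - d1 / (2.0 * c2n);  // parabola vertex
          if (tv > t0 && tv < t2) {
            double yv = y0 + d1 * (tv - t0) + c2n * (tv - t0) * (tv - t1);
            if (yv < ymin && tv >= wstart) { tmin = tv; ymin = yv; }
          }
        }
      }
      out(r, 2 * m) = tmin;
      out(r, 2 * m + 1) = ymin;
    }
  }
  return out;
}
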