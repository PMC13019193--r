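#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// State order: pathogen, neutrophil, monocyte, M1, M2, IL6, TGFb.
// Parameter order must match parameter_names() on the R side:
// 0 alpha1, 1 alpha2, 2 beta, 3 gamma1, 4 gamma2, 5 gamma3, 6 gamma4,
// 7 gamma5, 8 delta1, 9 delta2, 10 delta3, 11 mu1, 12 mu2, 13 mu3, 14 mu4,
// 15 Kn, 16 n_hill, 17 Cmax, 18 theta_eff, 19 kappa.

static const int NSP = 7;

struct Controller {
  bool active;
  double alpha, n, Kd;
  bool targets[4]; // mu3, delta3, mu2, gamma3
};

static inline double hill_multiplier(double il6, const Controller &c) {
  if (!c.active || c.alpha == 0.0) return 1.0;
  if (il6 <= 0.0) return 1.0;
  double num = std::pow(il6, c.n);
  double den = std::pow(c.Kd, c.n) + num;
  return 1.0 + c.alpha * num / den;
}

static void rhs(const double *yin, const double *p, const Controller &c,
                double *dy) {
  double y[NSP];
  for (int i = 0; i < NSP; ++i) y[i] = yin[i] > 0.0 ? yin[i] : 0.0;

  const double P = y[0], N = y[1], Mo = y[2], M1 = y[3], M2 = y[4],
               IL6 = y[5], TGF = y[6];

  double mult = hill_multiplier(IL6, c);
  double mu3 = p[13] * (c.active && c.targets[0] ? mult : 1.0);
  double delta3 = p[10] * (c.active && c.targets[1] ? mult : 1.0);
  double mu2 = p[12] * (c.active && c.targets[2] ? mult : 1.0);
  double gamma3 = p[5] * (c.active && c.targets[3] ? mult : 1.0);

  double eff = std::tanh(p[19] * (M1 - p[18]) / 2.0);
  double total = N + Mo + M1 + M2;
  double cap = 1.0 - total / p[17];
  if (cap < 0.0) cap = 0.0;

  double hill = 0.0;
  if (P > 0.0) {
    double Pn = std::pow(P, p[16]);
    hill = Pn / (Pn + std::pow(p[15], p[16]));
  }

  dy[0] = p[1] * M1 * P * eff - p[6] * N * P - delta3 * P;
  dy[1] = p[0] * hill * cap - p[7] * N * IL6 - p[11] * N;
  dy[2] = p[7] * N * IL6 - p[4] * Mo - mu2 * Mo;
  dy[3] = p[4] * Mo - gamma3 * M1 * TGF - mu3 * M1;
  dy[4] = gamma3 * M1 * TGF - p[14] * M2;
  dy[5] = p[2] * N - p[8] * IL6;
  dy[6] = p[3] * M1 * N - p[9] * TGF;
}

// Single-state RHS evaluation (exposes the C++ kinetics for equivalence
// checks against the pure-R derivatives()).
// [[Rcpp::export(name = ".rhs_core")]]
NumericVector rhs_core(NumericVector y, NumericVector params,
                       bool has_controller, double c_alpha, double c_n,
                       double c_Kd, LogicalVector c_targets) {
  Controller c;
  c.active = has_controller;
  c.alpha = c_alpha; c.n = c_n; c.Kd = c_Kd;
  for (int i = 0; i < 4; ++i) c.targets[i] = has_controller && c_targets[i];
  NumericVector dy(NSP);
  rhs(REAL(y), REAL(params), c, REAL(dy));
  return dy;
}

// Dormand-Prince 5(4) coefficients.
static const double A21 = 1.0 / 5.0;
static const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
static const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
static const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
                    A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
static const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
                    A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
                    A65 = -5103.0 / 18656.0;
static const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0,
                    B4 = 125.0 / 192.0, B5 = -2187.0 / 6784.0,
                    B6 = 11.0 / 84.0;
// 4th-order embedded solution
static const double E1 = 71.0 / 57600.0, E3 = -71.0 / 16695.0,
                    E4 = 71.0 / 1920.0, E5 = -17253.0 / 339200.0,
                    E6 = 22.0 / 525.0, E7 = -1.0 / 40.0;

// Integrate from t0 to t1 (no events inside), recording nothing; y updated
// in place. Returns number of accepted steps, throws on failure.
static long advance(double *y, double t0, double t1, const double *p,
                    const Controller &c, double rtol, double atol,
                    double &h, long max_steps) {
  if (t1 <= t0) return 0;
  double t = t0;
  double k1[NSP], k2[NSP], k3[NSP], k4[NSP], k5[NSP], k6[NSP], k7[NSP];
  double ytmp[NSP], y5[NSP];
  long nacc = 0, ntot = 0;
  bool have_k1 = false;

  while (t < t1) {
    if (++ntot > max_steps)
      stop("integrator failure: step budget exceeded at t = %f", t);
    double hstep = std::min(h, t1 - t);
    bool last = hstep >= t1 - t - 1e-14 * std::max(1.0, std::fabs(t1));
    if (hstep < 1e-13)
      stop("integrator failure: step size underflow at t = %f", t);

    if (!have_k1) { rhs(y, p, c, k1); have_k1 = true; }

    for (int i = 0; i < NSP; ++i) ytmp[i] = y[i] + hstep * A21 * k1[i];
    rhs(ytmp, p, c, k2);
    for (int i = 0; i < NSP; ++i)
      ytmp[i] = y[i] + hstep * (A31 * k1[i] + A32 * k2[i]);
    rhs(ytmp, p, c, k3);
    for (int i = 0; i < NSP; ++i)
      ytmp[i] = y[i] + hstep * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(ytmp, p, c, k4);
    for (int i = 0; i < NSP; ++i)
      ytmp[i] = y[i] + hstep * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                                A54 * k4[i]);
    rhs(ytmp, p, c, k5);
    for (int i = 0; i < NSP; ++i)
      ytmp[i] = y[i] + hstep * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                                A64 * k4[i] + A65 * k5[i]);
    rhs(ytmp, p, c, k6);
    for (int i = 0; i < NSP; ++i)
      y5[i] = y[i] + hstep * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                              B5 * k5[i] + B6 * k6[i]);
    rhs(y5, p, c, k7); // FSAL

    double errnorm = 0.0;
    for (int i = 0; i < NSP; ++i) {
      double err = hstep * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] +
                            E5 * k5[i] + E6 * k6[i] + E7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSP);

    if (errnorm <= 1.0) {
      t = last ? t1 : t + hstep;
      for (int i = 0; i < NSP; ++i) {
        // project the integrator's tiny negative excursions back to 0
        y[i] = y5[i] > 0.0 ? y5[i] : 0.0;
        k1[i] = k7[i];
      }
      ++nacc;
      double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h = hstep * std::min(5.0, std::max(0.2, fac));
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      h = hstep * std::max(0.1, fac);
      have_k1 = true; // k1 still valid at (t, y)
    }
    if (h > t1 - t0) h = t1 - t0;
  }
  return nacc;
}

// [[Rcpp::export(name = ".integrate_core")]]
List integrate_core(NumericVector y0, NumericVector params,
                    NumericVector out_times,
                    NumericVector event_times, IntegerVector event_species,
                    NumericVector event_amounts,
                    bool has_controller, double c_alpha, double c_n,
                    double c_Kd, LogicalVector c_targets,
                    double rtol, double atol, double max_steps) {
  Controller c;
  c.active = has_controller;
  c.alpha = c_alpha; c.n = c_n; c.Kd = c_Kd;
  for (int i = 0; i < 4; ++i) c.targets[i] = has_controller && c_targets[i];

  const int nout = out_times.size();
  const int nev = event_times.size();
  NumericMatrix states(nout, NSP);
  double y[NSP];
  for (int i = 0; i < NSP; ++i) y[i] = y0[i];

  // walk output times and event times together as ordered checkpoints
  double t = out_times[0];
  int iout = 0, iev = 0;
  long nacc = 0;
  double h = 1e-3;

  // apply any events scheduled at the start before the first record
  while (iev < nev && event_times[iev] <= t) {
    y[event_species[iev]] += event_amounts[iev];
    ++iev;
  }
  for (int i = 0; i < NSP; ++i) states(0, i) = y[i];
  iout = 1;

  while (iout < nout || iev < nev) {
    double tnext;
    bool is_event = false;
    if (iev < nev && (iout >= nout || event_times[iev] <= out_times[iout])) {
      tnext = event_times[iev];
      is_event = true;
    } else {
      tnext = out_times[iout];
    }
    nacc += advance(y, t, tnext, REAL(params), c, rtol, atol, h,
                    (long)max_steps);
    t = tnext;
    if (is_event) {
      // apply all events scheduled at this instant
      while (iev < nev && event_times[iev] == tnext) {
        y[event_species[iev]] += event_amounts[iev];
        ++iev;
      }
    }
    // record output(s) that coincide with t (post-event state by convention)
    while (iout < nout && out_times[iout] == t) {
      for (int i = 0; i < NSP; ++i) states(iout, i) = y[i];
      ++iout;
    }
  }

  return List::create(_["states"] = states, _["n_steps"] = (double)nacc);
}
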