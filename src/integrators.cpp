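#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step integrators for the tumor/CAR-T models with impulsive dosing.
// Populations are absolute cell counts, time is in days.  Dose times are
// pre-validated in R to sit exactly on the step grid and arrive here as
// step indices.  State stored at a dose step is the post-impulse (right)
// limit; T (and R) carry over unchanged across a jump.

struct Params {
  double rho_T, K, alpha_T, rho_C, g_T, alpha_C, g_C, tau_C, alpha_R;
};

static Params unpack(const NumericVector& p) {
  Params q;
  q.rho_T = p["rho_T"];  q.K = p["K"];        q.alpha_T = p["alpha_T"];
  q.rho_C = p["rho_C"];  q.g_T = p["g_T"];    q.alpha_C = p["alpha_C"];
  q.g_C = p["g_C"];      q.tau_C = p["tau_C"];
  q.alpha_R = p.containsElementNamed("alpha_R") ? double(p["alpha_R"]) : 0.0;
  return q;
}

// guard: clamp numerically tiny negatives, abort on real excursions or
// non-finite values so instability is never silently masked
static inline double guard(double v, double scale, double t, const char* what) {
  if (!R_finite(v))
    stop("non-finite %s at t = %g: integration aborted", what, t);
  if (v < 0.0) {
    if (v > -1e-9 * (scale + 1.0)) return 0.0;
    stop("%s became negative (%g) at t = %g: integration unstable at this dt",
         what, v, t);
  }
  return v;
}

static inline void rhs_ode(int model, const Params& q,
                           double T, double C, double R,
                           double& dT, double& dC, double& dR) {
  double eff = (model == 2) ? (1.0 - R) : 1.0;
  dT = q.rho_T * T * (1.0 - T / q.K) - q.alpha_T * eff * C * T;
  dC = (q.rho_C * eff * T / (q.g_T + T) -
        q.alpha_C * T / (q.g_C + C) - 1.0 / q.tau_C) * C;
  dR = (model == 2) ? q.alpha_R * C * (1.0 - R) : 0.0;
}

// model: 1 = base (T, C), 2 = resistance (T, C, R).
// dose_step[i] is the 0-based step index of dose i (0 = time 0).
// [[Rcpp::export]]
List integrate_ode_cpp(int model, NumericVector params,
                       double T0, double R0,
                       IntegerVector dose_step, NumericVector dose_amt,
                       double dt, int n_steps) {
  Params q = unpack(params);
  NumericVector Tv(n_steps + 1), Cv(n_steps + 1), Rv(n_steps + 1);
  double T = T0, C = 0.0, R = R0;
  int nd = dose_step.size(), next_dose = 0;

  while (next_dose < nd && dose_step[next_dose] == 0) {
    C += dose_amt[next_dose];
    ++next_dose;
  }
  Tv[0] = T; Cv[0] = C; Rv[0] = R;

  double k1T, k1C, k1R, k2T, k2C, k2R, k3T, k3C, k3R, k4T, k4C, k4R;
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    rhs_ode(model, q, T, C, R, k1T, k1C, k1R);
    rhs_ode(model, q, T + 0.5 * dt * k1T, C + 0.5 * dt * k1C,
            R + 0.5 * dt * k1R, k2T, k2C, k2R);
    rhs_ode(model, q, T + 0.5 * dt * k2T, C + 0.5 * dt * k2C,
            R + 0.5 * dt * k2R, k3T, k3C, k3R);
    rhs_ode(model, q, T + dt * k3T, C + dt * k3C, R + dt * k3R,
            k4T, k4C, k4R);
    double Tn = T + dt / 6.0 * (k1T + 2.0 * k2T + 2.0 * k3T + k4T);
    double Cn = C + dt / 6.0 * (k1C + 2.0 * k2C + 2.0 * k3C + k4C);
    double Rn = R + dt / 6.0 * (k1R + 2.0 * k2R + 2.0 * k3R + k4R);
    T = guard(Tn, q.K, t + dt, "tumor population");
    C = guard(Cn, q.K, t + dt, "CAR-T population");
    R = (model == 2) ? guard(Rn, 1.0, t + dt, "resistance strength") : R0;
    while (next_dose < nd && dose_step[next_dose] == i + 1) {
      C += dose_amt[next_dose];
      ++next_dose;
    }
    Tv[i + 1] = T; Cv[i + 1] = C; Rv[i + 1] = R;
    if ((i & 0xFFFF) == 0) checkUserInterrupt();
  }
  if (model == 2)
    return List::create(_["T"] = Tv, _["C"] = Cv, _["R"] = Rv);
  return List::create(_["T"] = Tv, _["C"] = Cv);
}

static inline double hist_T(const Params& q, double T0, double t) {
  // pre-treatment logistic flow, valid for t <= 0
  return q.K / (1.0 - (1.0 - q.K / T0) * std::exp(-q.rho_T * t));
}

static inline void rhs_dde(const Params& q, double T, double C,
                           double T_lag, double C_lag,
                           double& dT, double& dC) {
  dT = q.rho_T * T * (1.0 - T / q.K) - q.alpha_T * C * T;
  dC = q.rho_C * T_lag * C_lag / (q.g_T + T_lag) -
       (q.alpha_C * T / (q.g_C + C) + 1.0 / q.tau_C) * C;
}

// Method-of-steps Heun (2nd-order Runge-Kutta).  lag_steps = tau/dt, an
// exact integer (validated in R).  History: T from the logistic flow,
// C identically 0 on [-tau, 0) with C(0) seeded from the time-0 dose, so
// a lagged lookup landing exactly on a stored grid point (all do, since
// tau is a multiple of dt) takes the stored right-continuous value.
// [[Rcpp::export]]
List integrate_dde_cpp(NumericVector params, double T0, int lag_steps,
                       IntegerVector dose_step, NumericVector dose_amt,
                       double dt, int n_steps) {
  Params q = unpack(params);
  NumericVector Tv(n_steps + 1), Cv(n_steps + 1);
  double T = T0, C = 0.0;
  int nd = dose_step.size(), next_dose = 0;
  while (next_dose < nd && dose_step[next_dose] == 0) {
    C += dose_amt[next_dose];
    ++next_dose;
  }
  Tv[0] = T; Cv[0] = C;

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    int j1 = i - lag_steps;
    double Tl1 = (j1 < 0) ? hist_T(q, T0, j1 * dt) : Tv[j1];
    double Cl1 = (j1 < 0) ? 0.0 : Cv[j1];
    double k1T, k1C, k2T, k2C;
    rhs_dde(q, T, C, Tl1, Cl1, k1T, k1C);
    double Tp = T + dt * k1T, Cp = C + dt * k1C;
    int j2 = i + 1 - lag_steps;
    double Tl2, Cl2;
    if (lag_steps == 0) {          // tau = 0: lagged state is the current one
      Tl2 = Tp; Cl2 = Cp;
    } else if (j2 < 0) {
      Tl2 = hist_T(q, T0, j2 * dt); Cl2 = 0.0;
    } else {
      Tl2 = Tv[j2]; Cl2 = Cv[j2];
    }
    rhs_dde(q, Tp, Cp, Tl2, Cl2, k2T, k2C);
    double Tn = T + 0.5 * dt * (k1T + k2T);
    double Cn = C + 0.5 * dt * (k1C + k2C);
    T = guard(Tn, q.K, t + dt, "tumor population");
    C = guard(Cn, q.K, t + dt, "CAR-T population");
    while (next_dose < nd && dose_step[next_dose] == i + 1) {
      C += dose_amt[next_dose];
      ++next_dose;
    }
    Tv[i + 1] = T; Cv[i + 1] = C;
    if ((i & 0xFFFF) == 0) checkUserInterrupt();
  }
  return List::create(_["T"] = Tv, _["C"] = Cv);
}
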