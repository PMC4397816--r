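// Fixed-step RK4 integrator for the diauxic fermentation model.
//
// State: X  biomass (g/L)
//        G  glucose (g/L)
//        Xy xylose (g/L)
//        E  ethanol (g/L)
//        Xol xylitol (g/L)
//        I  xylose induction state in [0, 1]
//
// Ethanol is produced at a fixed yield on all sugar consumed, so
// E + Y_e * (G + Xy) is conserved by every RK4 stage and final ethanol
// equals yield x sugar consumed to machine precision on noise-free runs.

#include <Rcpp.h>
using namespace Rcpp;

struct Pars {
  double mu_max_g, mu_max_x, K_g, K_x, q_max_g, q_max_x;
  double Y_e, xylitol_frac;
  double E_thr, E_ceil, k_ind, glucose_gate, X_cap;
  double f_ac_g, f_ac_x;      // precomputed acetic inhibition factors
  double mu_eth_cap;          // ethanol conc. at which growth stops
  double detox_lag;           // h of furfural-imposed dormancy
};

static inline void deriv(double t, const double* s, double* d,
                         const Pars& p) {
  if (t < p.detox_lag) {      // furfural not yet detoxified: dormant
    for (int i = 0; i < 6; ++i) d[i] = 0.0;
    return;
  }
  double X = s[0], G = std::max(s[1], 0.0), Xy = std::max(s[2], 0.0);
  double E = s[3], I = std::min(std::max(s[5], 0.0), 1.0);
  double monod_g = G / (p.K_g + G);
  double monod_x = Xy / (p.K_x + Xy);
  double f_eth = std::max(0.0, 1.0 - E / p.mu_eth_cap);
  double f_cap = std::max(0.0, 1.0 - X / p.X_cap);  // N-limited ceiling
  double mu = (p.mu_max_g * monod_g * p.f_ac_g +
               p.mu_max_x * monod_x * I * p.f_ac_x) * f_eth * f_cap;
  double qg = p.q_max_g * monod_g * X;          // g/L/h
  double qx = p.q_max_x * monod_x * I * X;
  d[0] = mu * X;
  d[1] = -qg;
  d[2] = -qx;
  d[3] = p.Y_e * (qg + qx);
  d[4] = p.xylitol_frac * qx;
  if (G < p.glucose_gate) {
    double rep = 1.0 - std::max(0.0, E - p.E_thr) / (p.E_ceil - p.E_thr);
    d[5] = p.k_ind * (1.0 - I) * std::max(0.0, rep);
  } else {
    d[5] = 0.0;
  }
}

// [[Rcpp::export(name = ".ferment_rk4")]]
List ferment_rk4(NumericVector state0, NumericVector pars,
                 NumericVector times_out, double step) {
  Pars p;
  p.mu_max_g = pars["mu_max_glucose"];
  p.mu_max_x = pars["mu_max_xylose"];
  p.K_g = pars["K_glucose"];
  p.K_x = pars["K_xylose"];
  p.q_max_g = pars["q_max_glucose"];
  p.q_max_x = pars["q_max_xylose"];
  p.Y_e = pars["yield_ethanol_consumed"];
  p.xylitol_frac = pars["xylitol_fraction"];
  p.E_thr = pars["ethanol_repression_threshold"];
  p.E_ceil = pars["ethanol_repression_ceiling"];
  p.k_ind = pars["induction_rate"];
  p.glucose_gate = pars["glucose_gate"];
  p.X_cap = pars["biomass_cap"];
  p.f_ac_g = pars["f_acetic_glucose"];
  p.f_ac_x = pars["f_acetic_xylose"];
  p.mu_eth_cap = pars["ethanol_growth_cap"];
  p.detox_lag = pars["detox_lag"];

  const int ns = 6;
  double s[ns], k1[ns], k2[ns], k3[ns], k4[ns], tmp[ns];
  for (int i = 0; i < ns; ++i) s[i] = state0[i];

  int n_out = times_out.size();
  NumericMatrix out(n_out, ns);
  double t = 0.0;
  int iout = 0;
  double t_glc_dep = NA_REAL;   // dense-state glucose depletion (< gate)
  double t_xyl_onset = NA_REAL; // dense-state xylose fallen > 2 g/L
  double e_at_dep = NA_REAL;    // ethanol when glucose is depleted
  double xy0 = s[2];

  // emit any output times at t = 0
  while (iout < n_out && times_out[iout] <= t + 1e-9) {
    for (int i = 0; i < ns; ++i) out(iout, i) = s[i];
    ++iout;
  }
  double t_end = times_out[n_out - 1];
  while (t < t_end - 1e-9) {
    double h = std::min(step, t_end - t);
    deriv(t, s, k1, p);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
    deriv(t + 0.5 * h, tmp, k2, p);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
    deriv(t + 0.5 * h, tmp, k3, p);
    for (int i = 0; i < ns; ++i) tmp[i] = s[i] + h * k3[i];
    deriv(t + h, tmp, k4, p);
    for (int i = 0; i < ns; ++i)
      s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    // physical clamps: concentrations nonnegative, induction in [0, 1]
    for (int i = 1; i < 5; ++i) if (s[i] < 0.0) s[i] = 0.0;
    if (s[5] > 1.0) s[5] = 1.0;
    if (s[5] < 0.0) s[5] = 0.0;
    t += h;
    for (int i = 0; i < ns; ++i)
      if (!R_finite(s[i]))
        stop("non-finite state at t = %f (component %d)", t, i + 1);
    if (ISNA(t_glc_dep) && s[1] < p.glucose_gate) {
      t_glc_dep = t;
      e_at_dep = s[3];
    }
    if (ISNA(t_xyl_onset) && xy0 - s[2] > 2.0) t_xyl_onset = t;
    while (iout < n_out && times_out[iout] <= t + 1e-9) {
      for (int i = 0; i < ns; ++i) out(iout, i) = s[i];
      ++iout;
    }
  }
  colnames(out) = CharacterVector::create("X", "G", "Xy", "E", "Xol", "I");
  return List::create(_["states"] = out,
                      _["t_glucose_depleted"] = t_glc_dep,
                      _["t_xylose_onset"] = t_xyl_onset,
                      _["ethanol_at_glucose_depletion"] = e_at_dep);
}
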