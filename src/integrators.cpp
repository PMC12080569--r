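#include <Rcpp.h>
using namespace Rcpp;

// Plasma concentration (ng/mL) at arbitrary times by superposition of
// one-compartment first-order-absorption unit responses over a dose history.
// Each dose carries its own elimination rate constant (k = CL/F / V/F with the
// covariate value in force at that dose time), which keeps the superposition
// analytic when clearance drifts with body weight.
//
// times       observation times (days), any order
// dose_times  dose administration times (days), ascending
// dose_amt    dose amounts (ng)
// k_per_dose  elimination rate constant per dose (1/day)
// ka          absorption rate constant (1/day)
// v_f         apparent volume (L)
//
// Doses whose contribution is below exp(-45) of the initial amount are
// skipped; the cutoff uses the smallest k in the history so it is safe when
// k varies across doses.
// [[Rcpp::export]]
NumericVector conc_superposition_cpp(NumericVector times,
                                     NumericVector dose_times,
                                     NumericVector dose_amt,
                                     NumericVector k_per_dose,
                                     double ka,
                                     double v_f) {
  const int nt = times.size();
  const int nd = dose_times.size();
  NumericVector out(nt);
  if (nd == 0) return out;
  if (dose_amt.size() != nd || k_per_dose.size() != nd)
    stop("dose_amt and k_per_dose must have one entry per dose");

  double kmin = R_PosInf;
  for (int j = 0; j < nd; ++j) {
    if (k_per_dose[j] <= 0.0 || !R_finite(k_per_dose[j]))
      stop("elimination rate constants must be positive and finite");
    if (k_per_dose[j] < kmin) kmin = k_per_dose[j];
  }
  const double cutoff = 45.0;

  for (int i = 0; i < nt; ++i) {
    const double t = times[i];
    double c = 0.0;
    // last dose administered at or before t
    int j = nd - 1;
    while (j >= 0 && dose_times[j] > t) --j;
    for (; j >= 0; --j) {
      const double dt = t - dose_times[j];
      if (kmin * dt > cutoff) break;  // older doses are negligible
      const double k = k_per_dose[j];
      const double a = dose_amt[j] / v_f;  // ng/L
      double u;
      if (std::abs(ka - k) < 1e-8 * ka) {
        // limiting equal-rates form: ka * t * exp(-ka t)
        u = a * ka * dt * std::exp(-ka * dt);
      } else {
        u = a * ka / (ka - k) * (std::exp(-k * dt) - std::exp(-ka * dt));
      }
      c += u;
    }
    out[i] = c / 1000.0;  // ng/L -> ng/mL
  }
  return out;
}

// Exponential-update integration of the linear HbA1c turnover ODE
//   dH/dt = kin - Efc(t) * (H - floor) / (ref - floor) - kout * H,
// with kin = kout * h0 and Efc piecewise constant on a grid. Within each
// interval the ODE has constant coefficients, so the update
//   H <- Hss + (H - Hss) * exp(-b * dt)
// is exact for the discretised drive.
//
// grid   interval breakpoints (days), ascending, grid[0] is the start time
// efc    Emax-model effect (HbA1c %/day) per interval, length = len(grid)-1
// out_times  sorted times within [grid[0], grid[end]] at which to report H
// [[Rcpp::export]]
NumericVector hba1c_exponential_cpp(double h0,
                                    double kout,
                                    NumericVector grid,
                                    NumericVector efc,
                                    double floor_level,
                                    double ref_level,
                                    NumericVector out_times) {
  const int m = efc.size();
  if (grid.size() != m + 1) stop("grid must have length(efc) + 1 breakpoints");
  const int nt = out_times.size();
  NumericVector out(nt);
  if (kout <= 0.0) stop("kout must be positive");
  const double span = ref_level - floor_level;
  if (span <= 0.0) stop("reference baseline must exceed the floor");

  const double kin = kout * h0;
  double h = h0;
  double tcur = grid[0];
  int iout = 0;

  while (iout < nt && out_times[iout] <= tcur + 1e-12) {
    out[iout++] = h;
  }

  for (int i = 0; i < m && iout < nt; ++i) {
    const double tend = grid[i + 1];
    const double b = kout + efc[i] / span;
    const double a = kin + efc[i] * floor_level / span;
    const double hss = a / b;
    // report any output time falling inside this interval
    while (iout < nt && out_times[iout] <= tend + 1e-12) {
      const double dt = out_times[iout] - tcur;
      out[iout] = hss + (h - hss) * std::exp(-b * dt);
      ++iout;
    }
    h = hss + (h - hss) * std::exp(-b * (tend - tcur));
    tcur = tend;
  }
  if (iout < nt) stop("output times extend beyond the integration grid");
  return out;
}
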