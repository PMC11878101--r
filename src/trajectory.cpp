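#include <Rcpp.h>
using namespace Rcpp;

// Turnover kinetics of neonatal bilirubin:
//   dB/dt = k_in0 * exp(-lambda * t) - k_out_max * t^g / (t50^g + t^g) * B
// t is postnatal age in hours. Production declines exponentially from its
// value at birth; elimination matures along a sigmoid (Hill) curve.
static inline double deriv(double t, double B, double kin0, double lambda,
                           double kout_max, double t50, double g) {
  double kout = 0.0;
  if (t > 0.0) {
    double tg = std::pow(t, g);
    kout = kout_max * tg / (std::pow(t50, g) + tg);
  }
  return kin0 * std::exp(-lambda * t) - kout * B;
}

// Classical RK4 on a fixed internal grid (step h), with cubic Hermite dense
// output at the requested times. The internal grid does not depend on the
// requested times, so results at a given time are invariant to refinement
// of the requested grid and bitwise reproducible across calls.
// [[Rcpp::export(name = ".traj_rk4")]]
NumericVector traj_rk4(NumericVector times, double B0, double kin0,
                       double lambda, double kout_max, double t50, double g,
                       double h = 0.125) {
  int m = times.size();
  NumericVector out(m);
  if (m == 0) return out;
  double tmax = times[m - 1];
  for (int i = 0; i < m; ++i) {
    if (!R_FINITE(times[i]) || times[i] < 0.0)
      stop("trajectory times must be finite and nonnegative");
    if (i > 0 && times[i] < times[i - 1])
      stop("trajectory times must be sorted increasingly");
  }
  long nsteps = (long)std::ceil(tmax / h - 1e-12);

  double B = B0;
  double t = 0.0;
  double f0 = deriv(0.0, B, kin0, lambda, kout_max, t50, g);
  int i = 0;
  // emit any requests at t = 0
  while (i < m && times[i] <= 0.0) out[i++] = B;

  for (long k = 0; k < nsteps && i < m; ++k) {
    double t1 = (k + 1) * h;
    double k1 = f0;
    double k2 = deriv(t + h / 2, B + h / 2 * k1, kin0, lambda, kout_max, t50, g);
    double k3 = deriv(t + h / 2, B + h / 2 * k2, kin0, lambda, kout_max, t50, g);
    double k4 = deriv(t1, B + h * k3, kin0, lambda, kout_max, t50, g);
    double B1 = B + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4);
    double f1 = deriv(t1, B1, kin0, lambda, kout_max, t50, g);
    if (!R_FINITE(B1)) stop("integrator failure: non-finite state at t=%f", t1);
    // Hermite interpolation inside [t, t1]
    while (i < m && times[i] <= t1 + 1e-12) {
      double s = (times[i] - t) / h;
      double s2 = s * s, s3 = s2 * s;
      double h00 = 2 * s3 - 3 * s2 + 1;
      double h10 = s3 - 2 * s2 + s;
      double h01 = -2 * s3 + 3 * s2;
      double h11 = s3 - s2;
      out[i] = h00 * B + h10 * h * f0 + h01 * B1 + h11 * h * f1;
      ++i;
    }
    B = B1;
    f0 = f1;
    t = t1;
  }
  while (i < m) out[i++] = B;  // guard against rounding at tmax
  for (int j = 0; j < m; ++j) if (out[j] < 0.0) out[j] = 0.0;
  return out;
}
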