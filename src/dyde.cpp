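#include <Rcpp.h>
using namespace Rcpp;

// Exact per-interval solution of dy/dt = a*u(t) - b*y + c on a uniform grid.
// u is linearly interpolated between samples (foh = true) or held at the
// left sample (foh = false).  Works for any real b (unstable b < 0 allowed).
static inline void interval_weights(double b, double h,
                                    double &E, double &I0, double &I1) {
  double bh = b * h;
  if (std::fabs(bh) < 1e-6) {
    // series expansions; avoid catastrophic cancellation at small |b|h
    E  = std::exp(-bh);
    I0 = h * (1.0 - bh / 2.0 + bh * bh / 6.0 - bh * bh * bh / 24.0);
    I1 = h * h * (0.5 - bh / 6.0 + bh * bh / 24.0 - bh * bh * bh / 120.0);
  } else {
    E  = std::exp(-bh);
    I0 = -std::expm1(-bh) / b;       // (1 - e^{-bh}) / b
    I1 = (h - I0) / b;               // int_0^h e^{-b(h-s)} s ds
  }
}

// [[Rcpp::export]]
NumericVector cpp_simulate_foh(double a, double b, double c, double x0,
                               NumericVector u, double dt, bool foh) {
  int n = u.size();
  NumericVector y(n);
  y[0] = x0;
  double E, I0, I1;
  interval_weights(b, dt, E, I0, I1);
  for (int k = 0; k + 1 < n; ++k) {
    double slope = foh ? (u[k + 1] - u[k]) / dt : 0.0;
    y[k + 1] = E * y[k] + a * (u[k] * I0 + slope * I1) + c * I0;
  }
  return y;
}

// Basis responses for fixed b: columns are y for (a,c,x0) = e_i.
// The model output is linear in (a, c, x0), enabling variable projection.
// [[Rcpp::export]]
NumericMatrix cpp_sim_basis(double b, NumericVector u, double dt, bool foh) {
  int n = u.size();
  NumericMatrix Y(n, 3);
  double E, I0, I1;
  interval_weights(b, dt, E, I0, I1);
  Y(0, 0) = 0.0; Y(0, 1) = 0.0; Y(0, 2) = 1.0;
  for (int k = 0; k + 1 < n; ++k) {
    double slope = foh ? (u[k + 1] - u[k]) / dt : 0.0;
    double fu = u[k] * I0 + slope * I1;
    Y(k + 1, 0) = E * Y(k, 0) + fu;   // response to a = 1
    Y(k + 1, 1) = E * Y(k, 1) + I0;   // response to c = 1
    Y(k + 1, 2) = E * Y(k, 2);        // response to x0 = 1
  }
  return Y;
}

// positive remainder of t modulo P (avoids fmod: glibc >= 2.38 symbol)
static inline double pos_mod(double t, double P) {
  double m = t - P * std::floor(t / P);
  if (m >= P) m -= P;   // guard against rounding at the boundary
  return m;
}

static inline double ps_theta(double tm, double A_half1, double p1, double p2) {
  // phase argument of the active half-cycle sinusoid (phi added by caller)
  if (tm < A_half1)
    return 2.0 * M_PI / p1 * tm;
  return 2.0 * M_PI / p2 * (tm - p1 / 2.0 + p2 / 2.0);
}

// [[Rcpp::export]]
NumericVector cpp_pseudo_sine_eval(double A, double phi1, double p1, double p2,
                                   NumericVector times) {
  int n = times.size();
  NumericVector out(n);
  double P = (p1 + p2) / 2.0;
  for (int i = 0; i < n; ++i) {
    double tm = pos_mod(times[i], P);
    out[i] = A * std::sin(ps_theta(tm, p1 / 2.0, p1, p2) + phi1);
  }
  return out;
}

// remove the OLS straight line from x (in place); tc is centered time,
// stt = sum(tc^2)
static inline void detrend_vec(std::vector<double> &x,
                               const std::vector<double> &tc, double stt) {
  int n = x.size();
  double mean = 0.0, cross = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  for (int i = 0; i < n; ++i) cross += tc[i] * x[i];
  double slope = (stt > 0.0) ? cross / stt : 0.0;
  for (int i = 0; i < n; ++i) x[i] -= mean + slope * tc[i];
}

// Exhaustive least-squares grid search over (p1, p2, phi); amplitude A >= 0
// by closed form.  The candidate waveform is fitted jointly with an
// intercept and linear trend (both data and waveform are detrended), so a
// trend-free pseudo-sine on the grid is recovered exactly.  Ties broken
// toward smallest (p1, p2, phi).  Returns c(A, phi, p1, p2, l2_error).
// [[Rcpp::export]]
NumericVector cpp_fit_pseudo_sine(NumericVector y, NumericVector times,
                                  NumericVector p_grid, int n_phase) {
  int n = y.size(), np = p_grid.size();
  double yy = 0.0;
  for (int i = 0; i < n; ++i) yy += y[i] * y[i];
  std::vector<double> tc(n);
  double tmean = 0.0, stt = 0.0;
  for (int i = 0; i < n; ++i) tmean += times[i];
  tmean /= n;
  for (int i = 0; i < n; ++i) { tc[i] = times[i] - tmean; stt += tc[i] * tc[i]; }

  double best_r2 = R_PosInf, best_A = 0.0, best_phi = 0.0;
  double best_p1 = p_grid[0], best_p2 = p_grid[0];
  std::vector<double> st(n), ct(n);

  for (int i1 = 0; i1 < np; ++i1) {
    double p1 = p_grid[i1];
    for (int i2 = 0; i2 < np; ++i2) {
      double p2 = p_grid[i2];
      double P = (p1 + p2) / 2.0;
      for (int i = 0; i < n; ++i) {
        double tm = pos_mod(times[i], P);
        double th = ps_theta(tm, p1 / 2.0, p1, p2);
        st[i] = std::sin(th);
        ct[i] = std::cos(th);
      }
      detrend_vec(st, tc, stt);
      detrend_vec(ct, tc, stt);
      double ss = 0.0, cc = 0.0, sc = 0.0, ys = 0.0, yc = 0.0;
      for (int i = 0; i < n; ++i) {
        ss += st[i] * st[i];
        cc += ct[i] * ct[i];
        sc += st[i] * ct[i];
        ys += y[i] * st[i];
        yc += y[i] * ct[i];
      }
      for (int ip = 0; ip < n_phase; ++ip) {
        double phi = 2.0 * M_PI * ip / n_phase;
        double cph = std::cos(phi), sph = std::sin(phi);
        // s_phi(t) = cos(phi) sin(theta) + sin(phi) cos(theta)
        double ysd = cph * ys + sph * yc;
        double ssd = cph * cph * ss + 2.0 * cph * sph * sc + sph * sph * cc;
        double A = (ssd > 0.0) ? ysd / ssd : 0.0;
        if (A < 0.0) A = 0.0;
        double r2 = yy - 2.0 * A * ysd + A * A * ssd;
        if (r2 < best_r2 - 1e-12) {
          best_r2 = r2; best_A = A; best_phi = phi;
          best_p1 = p1; best_p2 = p2;
        }
      }
    }
  }
  if (best_r2 < 0.0) best_r2 = 0.0;  // numerical guard near-perfect fits
  return NumericVector::create(best_A, best_phi, best_p1, best_p2,
                               std::sqrt(best_r2));
}
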