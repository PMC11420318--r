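// Core stochastic kernels: Chambers-Mulligan-Stuck sampling of symmetric
// alpha-stable variates and Euler-type forward simulation of the Levy-flight
// accumulation process.  All randomness goes through R's RNG so that
// set.seed() in R gives bit-reproducible output.
#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static const double GAMMA_NOISE = 0.70710678118654752440; // 1/sqrt(2)

// One standard (scale 1) symmetric alpha-stable draw, CMS transformation.
// For beta = 0 the CMS formula reduces to
//   sin(alpha U) / cos(U)^{1/alpha} * (cos((1-alpha) U) / W)^{(1-alpha)/alpha}
// with U ~ U(-pi/2, pi/2), W ~ Exp(1); evaluated in log form with the
// alpha-dependent exponents precomputed by the caller (inv_a = 1/alpha,
// r_a = (1-alpha)/alpha).  Both cosine arguments lie in (-pi/2, pi/2) so the
// logs are well defined.
static inline double cms_stable(double alpha, double inv_a, double r_a) {
  double u = M_PI * (unif_rand() - 0.5);
  double w = exp_rand();
  double s = std::sin(alpha * u);
  double lc = std::log(std::cos(u));
  double lc2 = std::log(std::cos((1.0 - alpha) * u));
  return s * std::exp(-inv_a * lc + r_a * (lc2 - std::log(w)));
}

// [[Rcpp::export(name = ".rstable_sym_cpp")]]
NumericVector rstable_sym_cpp(int n, double alpha, double gamma_, double delta) {
  NumericVector out(n);
  if (std::fabs(alpha - 2.0) < 1e-12) {
    double sd = gamma_ * M_SQRT2; // Stable(2, 0, gamma) = N(delta, 2 gamma^2)
    for (int i = 0; i < n; ++i) out[i] = delta + sd * norm_rand();
    return out;
  }
  if (std::fabs(alpha - 1.0) < 1e-12) { // Cauchy limit
    for (int i = 0; i < n; ++i)
      out[i] = delta + gamma_ * std::tan(M_PI * (unif_rand() - 0.5));
    return out;
  }
  double inv_a = 1.0 / alpha, r_a = (1.0 - alpha) / alpha;
  for (int i = 0; i < n; ++i)
    out[i] = delta + gamma_ * cms_stable(alpha, inv_a, r_a);
  return out;
}

// Simulate n trials of the Levy-flight accumulator.
// Returns a matrix with columns (choice, rt, decision_time); choice is
// 1 = upper, 0 = lower, NA = censored at t_max after all resampling attempts.
// resample_max = 0 means "flag, do not resample".
// [[Rcpp::export(name = ".simulate_trials_cpp")]]
NumericMatrix simulate_trials_cpp(int n, double v, double a, double zr,
                                  double t0, double alpha, double sv,
                                  double szr, double st, double dt,
                                  double t_max, int resample_max) {
  NumericMatrix out(n, 3);
  const bool gaussian = std::fabs(alpha - 2.0) < 1e-12;
  const bool cauchy = !gaussian && std::fabs(alpha - 1.0) < 1e-12;
  const double jump_scale = gaussian ? std::sqrt(dt)
                                     : GAMMA_NOISE * std::pow(dt, 1.0 / alpha);
  const double inv_a = 1.0 / alpha, r_a = (1.0 - alpha) / alpha;
  const long max_steps = (long)std::ceil(t_max / dt);
  for (int i = 0; i < n; ++i) {
    double choice = NA_REAL, dtime = NA_REAL, tnd = t0;
    for (int attempt = 0; attempt <= resample_max; ++attempt) {
      double vt = (sv > 0.0) ? v + sv * norm_rand() : v;
      double z0 = (szr > 0.0) ? (zr + szr * (unif_rand() - 0.5)) * a : zr * a;
      tnd = (st > 0.0) ? t0 + st * (unif_rand() - 0.5) : t0;
      double x = z0, drift = vt * dt;
      long step = 0;
      while (step < max_steps) {
        double e = gaussian ? norm_rand()
                 : cauchy   ? std::tan(M_PI * (unif_rand() - 0.5))
                            : cms_stable(alpha, inv_a, r_a);
        x += drift + jump_scale * e;
        ++step;
        if (x >= a) { choice = 1.0; dtime = step * dt; break; }
        if (x <= 0.0) { choice = 0.0; dtime = step * dt; break; }
      }
      if (!ISNA(choice)) break;
    }
    out(i, 0) = choice;
    out(i, 1) = ISNA(choice) ? NA_REAL : dtime + tnd;
    out(i, 2) = dtime;
  }
  return out;
}
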