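#include <Rcpp.h>
#include "lambertw.h"

// Cumulative hazard and exact firing-time sampling for a total propensity
// of the form  a(s) = A + b*exp(-mu*s) + g*exp(mu*s),  s in [0, tau]:
//   A — volume-independent channels (orders 0/1, transcription, unbinding,
//       quasi-static Michaelis-Menten),
//   b — inverse-volume channels evaluated at s = 0 (bimolecular, binding),
//   g — proportional-volume channels at s = 0 (concentration influxes),
//   mu — exponential volume growth rate ln(2)/T.

static inline double hazard(double A, double b, double g, double mu,
                            double tau) {
  if (mu <= 0.0) return (A + b + g) * tau;
  double L = A * tau;
  if (b > 0.0) L += b * (-std::expm1(-mu * tau)) / mu;
  if (g > 0.0) L += g * std::expm1(mu * tau) / mu;
  return L;
}

// [[Rcpp::export]]
double cpp_survival_integral(double A, double b, double g, double mu,
                             double tau) {
  if (A < 0 || b < 0 || g < 0 || tau < 0)
    Rcpp::stop("survival_integral: A, b, g, tau must be >= 0");
  return hazard(A, b, g, mu, tau);
}

// Solve Lambda(tau) = L. Returns +Inf for NO_FIRING (bounded total hazard
// when A = g = 0 and mu*L/b >= 1, or zero total propensity).
double sample_tau(double A, double b, double g, double mu, double r) {
  if (!(r > 0.0 && r < 1.0)) Rcpp::stop("uniform draw r must lie in (0,1)");
  if (A < 0 || b < 0 || g < 0) Rcpp::stop("negative propensity total");
  double tot = A + b + g;
  if (tot <= 0.0) return R_PosInf;
  double L = -std::log(r);
  if (mu <= 0.0) return L / tot;

  double tau;
  if (g == 0.0) {
    if (b == 0.0) {
      return L / A;  // classic SSA limit, exact
    } else if (A == 0.0) {
      double x = mu * L / b;
      if (x >= 1.0) return R_PosInf;        // hazard bounded by b/mu
      tau = -std::log1p(-x) / mu;
    } else {
      // closed form via principal-branch Lambert W:
      //   tau = (L - b/mu)/A + W0((b/A) * exp(-mu*(L - b/mu)/A)) / mu
      double alpha = (mu * L - b) / A;      // = mu*(L - b/mu)/A
      double y = std::log(b / A) - alpha;   // W argument is exp(y)
      double w = lambert_w0_exp(y);
      tau = (alpha + w) / mu;
      if (!(tau >= 0.0)) tau = 0.0;
    }
    // Newton polish on the hazard residual (precision safeguard: delayed
    // queues starve non-delayed channels if tau is systematically high).
    // The target is relative to L itself, not 1 + L: for r near 1 the
    // hazard is tiny and an absolute criterion would leave the waiting
    // time orders of magnitude less accurate than the contract.
    for (int it = 0; it < 8; ++it) {
      double f = hazard(A, b, g, mu, tau) - L;
      if (std::fabs(f) <= 1e-14 * L) break;
      double fp = A + b * std::exp(-mu * tau);
      if (fp <= 0.0) break;
      double t2 = tau - f / fp;
      if (t2 < 0.0) t2 = 0.5 * tau;
      if (t2 == tau) break;
      tau = t2;
    }
  } else {
    // g > 0: hazard is unbounded and strictly increasing; safeguarded
    // Newton with bisection fallback on a doubling bracket.
    double lo = 0.0, hi = L / tot;
    if (hi <= 0.0) hi = 1e-12;
    while (hazard(A, b, g, mu, hi) < L) {
      lo = hi;
      hi *= 2.0;
      if (hi > 1e18) break;
    }
    tau = 0.5 * (lo + hi);
    for (int it = 0; it < 200; ++it) {
      double f = hazard(A, b, g, mu, tau) - L;
      if (std::fabs(f) <= 1e-14 * L) break;
      if (f > 0.0) hi = tau; else lo = tau;
      double fp = A + b * std::exp(-mu * tau) + g * std::exp(mu * tau);
      double t2 = tau - f / fp;
      tau = (t2 > lo && t2 < hi) ? t2 : 0.5 * (lo + hi);
      if (hi - lo < 1e-16 * (1.0 + hi)) break;
    }
  }
  return tau;
}

// [[Rcpp::export]]
double cpp_sample_firing_time(double A, double b, double g, double mu,
                              double r) {
  return sample_tau(A, b, g, mu, r);
}

// [[Rcpp::export]]
double cpp_lambert_w0(double x) { return lambert_w0(x); }
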