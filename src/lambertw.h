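#ifndef GROWSSA_LAMBERTW_H
#define GROWSSA_LAMBERTW_H

#include <cmath>

// Principal branch W0 of the Lambert function, the solution of w*e^w = x
// for x >= -1/e. Halley iteration on a piecewise initial guess; absolute
// tolerance far below the 1e-10 residual contract of the firing-time
// sampler, which additionally polishes with Newton on the hazard itself.
inline double lambert_w0(double x) {
  if (!(x >= -0.3678794411714423)) {
    if (x > -0.36787944117144233) x = -0.36787944117144232;  // clip roundoff
    else return NAN;
  }
  double w;
  if (x < -0.25) {
    // branch-point expansion around x = -1/e
    double p = std::sqrt(2.0 * (1.0 + 2.718281828459045 * x));
    w = -1.0 + p - p * p / 3.0 + 11.0 * p * p * p / 72.0;
  } else if (x < 2.0) {
    w = x * (1.0 - x + 1.5 * x * x) / (1.0 + 0.5 * x);  // crude near 0
    if (w < -0.9) w = -0.9;
  } else {
    double lx = std::log(x);
    double llx = std::log(lx);
    w = lx - llx + llx / lx;
  }
  for (int it = 0; it < 50; ++it) {
    double ew = std::exp(w);
    double f = w * ew - x;
    double w1 = w + 1.0;
    double denom = ew * w1 - (w + 2.0) * f / (2.0 * w1);
    double dw = f / denom;
    w -= dw;
    if (std::fabs(dw) < 1e-14 * (1.0 + std::fabs(w))) break;
  }
  return w;
}

// W0(exp(y)) without overflow for large y (the sampler can produce
// arguments like exp(1e6) when b/A is huge and mu is small).
inline double lambert_w0_exp(double y) {
  if (y < 700.0) return lambert_w0(std::exp(y));
  // solve w + log(w) = y; asymptotic start
  double ly = std::log(y);
  double w = y - ly + ly / y;
  for (int it = 0; it < 30; ++it) {
    double f = w + std::log(w) - y;
    double dw = f / (1.0 + 1.0 / w);
    w -= dw;
    if (std::fabs(dw) < 1e-14 * w) break;
  }
  return w;
}

#endif
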