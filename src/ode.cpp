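#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fixed-step RK4 integrators for the deterministic reference models.
// Kept independent of the stochastic engine: concentrations in uM,
// explicit stepping, cubic-Hermite history interpolation for the delay
// term. Negative excursions are clipped to zero (clip-and-warn).

// ---- negative autoregulation (mRNA, protein, dimer, bound promoter) ----

struct ARp {
  double a, b, r1, r2, c, d, K1, K2, fac, G0;
};

static inline void ar_rhs(const ARp& p, const double y[4], double mlag,
                          double dy[4]) {
  double m = y[0], P = y[1], dm = y[2], Gb = y[3];
  double Gf = p.G0 - Gb;
  if (Gf < 0) Gf = 0;
  dy[0] = p.a * (Gf + p.fac * Gb) - p.r1 * m;
  dy[1] = p.b * mlag - p.r2 * P - 2.0 * p.c * P * P + 2.0 * p.d * dm;
  dy[2] = p.c * P * P - p.d * dm - p.K1 * dm * Gf + p.K2 * Gb;
  dy[3] = p.K1 * dm * Gf - p.K2 * Gb;
}

// delay = 0: plain ODE (the translation term uses the current stage's
// own mRNA). delay > 0: mRNA(t - delay) with lag_steps = delay/h exact.
// [[Rcpp::export]]
List cpp_autoreg_ode(NumericVector pars, double G0, NumericVector y0,
                     double delay, double t_end, double h, double out_dt) {
  ARp p{pars["a"], pars["b"], pars["r1"], pars["r2"], pars["c"],
        pars["d"], pars["K1"], pars["K2"], pars["fac"], G0};
  long nsteps = (long)std::ceil(t_end / h - 1e-9);
  h = t_end / nsteps;
  long L = 0;
  if (delay > 0) {
    L = (long)std::floor(delay / h + 0.5);
    if (L < 1) stop("integration step larger than the delay");
    h = delay / L;
    nsteps = (long)std::ceil(t_end / h - 1e-9);
  }
  long every = (long)std::floor(out_dt / h + 0.5);
  if (every < 1) every = 1;
  long nout = nsteps / every + 1;
  NumericMatrix out(nout, 5);
  double y[4] = {y0[0], y0[1], y0[2], y0[3]};
  // ring buffers over the delay window for mRNA and its derivative
  std::vector<double> hm, hd;
  if (L > 0) { hm.assign(L + 1, y[0]); hd.assign(L + 1, 0.0); }
  long oidx = 0, clipped = 0;
  out(0, 0) = 0;
  for (int s = 0; s < 4; ++s) out(0, s + 1) = y[s];
  ++oidx;
  double k1[4], k2[4], k3[4], k4[4], yt[4];
  for (long i = 0; i < nsteps; ++i) {
    double m0, mm, m1;  // lagged mRNA at t, t + h/2, t + h
    if (L > 0) {
      long j0 = i - L, j1 = i - L + 1;
      double a0 = (j0 < 0) ? y0[0] : hm[j0 % (L + 1)];
      double d0 = (j0 < 0) ? 0.0 : hd[j0 % (L + 1)];
      // the R wrapper enforces L >= 20, so j1 <= i - 19 is always a
      // previously stored node
      double a1 = (j1 < 0) ? y0[0] : hm[j1 % (L + 1)];
      double d1 = (j1 < 0) ? 0.0 : hd[j1 % (L + 1)];
      m0 = a0;
      m1 = a1;
      mm = 0.5 * (a0 + a1) + h * (d0 - d1) / 8.0;  // cubic Hermite midpoint
    } else {
      m0 = mm = m1 = 0;  // unused; plain branch below
    }
    if (L > 0) {
      ar_rhs(p, y, m0, k1);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + 0.5 * h * k1[s];
      ar_rhs(p, yt, mm, k2);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + 0.5 * h * k2[s];
      ar_rhs(p, yt, mm, k3);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + h * k3[s];
      ar_rhs(p, yt, m1, k4);
    } else {
      ar_rhs(p, y, y[0], k1);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + 0.5 * h * k1[s];
      ar_rhs(p, yt, yt[0], k2);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + 0.5 * h * k2[s];
      ar_rhs(p, yt, yt[0], k3);
      for (int s = 0; s < 4; ++s) yt[s] = y[s] + h * k3[s];
      ar_rhs(p, yt, yt[0], k4);
    }
    if (L > 0) {  // store history of step i before overwriting the slot
      hm[i % (L + 1)] = y[0];
      hd[i % (L + 1)] = k1[0];
    }
    for (int s = 0; s < 4; ++s) {
      y[s] += h / 6.0 * (k1[s] + 2 * k2[s] + 2 * k3[s] + k4[s]);
      if (y[s] < 0) { y[s] = 0; ++clipped; }
    }
    if (!R_FINITE(y[1])) stop("integrator failure: non-finite state");
    if ((i + 1) % every == 0 && oidx < nout) {
      out(oidx, 0) = (i + 1) * h;
      for (int s = 0; s < 4; ++s) out(oidx, s + 1) = y[s];
      ++oidx;
    }
  }
  return List::create(_["series"] = out, _["h"] = h,
                      _["clipped"] = (double)clipped, _["nout"] = (double)oidx);
}

// ---- dynamic flux-balance model (M1, M2, M3, mRNAs, enzymes) ----------

// dosage is a right-continuous step function given by breakpoints
// (dos_t ascending, starting at 0) with values dosA/dosB in uM; frozen
// over each RK4 step (breakpoints are minutes apart, h is ~0.02 s).
// [[Rcpp::export]]
List cpp_flux_ode(NumericVector pars, NumericVector y0, NumericVector dos_t,
                  NumericVector dosA, NumericVector dosB, double t_end,
                  double h, double out_dt) {
  double influx = pars["influx"], r3 = pars["r3"], r1 = pars["r1"],
         r2 = pars["r2"], Kc = pars["Kc"], Km = pars["Km"], a = pars["a"],
         b = pars["b"], mu = pars["mu"];
  long nsteps = (long)std::ceil(t_end / h - 1e-9);
  h = t_end / nsteps;
  long every = (long)std::floor(out_dt / h + 0.5);
  if (every < 1) every = 1;
  long nout = nsteps / every + 1;
  NumericMatrix out(nout, 10);
  double y[7];
  for (int s = 0; s < 7; ++s) y[s] = y0[s];
  int nb = dos_t.size(), bi = 0;
  long oidx = 0, clipped = 0;
  auto rhs = [&](const double yy[7], double dA, double dB, double dy[7]) {
    double M1 = yy[0], M2 = yy[1], M3 = yy[2], Ra = yy[3], Ea = yy[4],
           Rb = yy[5], Eb = yy[6];
    double v1 = Kc * Ea * M1 / (Km + M1);
    double v2 = Kc * Eb * M2 / (Km + M2);
    dy[0] = influx - v1 - r3 * M1 - mu * M1;
    dy[1] = v1 - v2 - mu * M2;
    dy[2] = v2 - r3 * M3 - mu * M3;
    dy[3] = a * dA - r1 * Ra - mu * Ra;
    dy[4] = b * Ra - r2 * Ea - mu * Ea;
    dy[5] = a * dB - r1 * Rb - mu * Rb;
    dy[6] = b * Rb - r2 * Eb - mu * Eb;
  };
  double k1[7], k2[7], k3[7], k4[7], yt[7];
  out(0, 0) = 0;
  for (int s = 0; s < 7; ++s) out(0, s + 1) = y[s];
  out(0, 8) = dosA[0]; out(0, 9) = dosB[0];
  ++oidx;
  for (long i = 0; i < nsteps; ++i) {
    double t = i * h;
    while (bi + 1 < nb && dos_t[bi + 1] <= t) ++bi;
    double dA = dosA[bi], dB = dosB[bi];
    rhs(y, dA, dB, k1);
    for (int s = 0; s < 7; ++s) yt[s] = y[s] + 0.5 * h * k1[s];
    rhs(yt, dA, dB, k2);
    for (int s = 0; s < 7; ++s) yt[s] = y[s] + 0.5 * h * k2[s];
    rhs(yt, dA, dB, k3);
    for (int s = 0; s < 7; ++s) yt[s] = y[s] + h * k3[s];
    rhs(yt, dA, dB, k4);
    for (int s = 0; s < 7; ++s) {
      y[s] += h / 6.0 * (k1[s] + 2 * k2[s] + 2 * k3[s] + k4[s]);
      if (y[s] < 0) { y[s] = 0; ++clipped; }
    }
    if (!R_FINITE(y[1])) stop("integrator failure: non-finite state");
    if ((i + 1) % every == 0 && oidx < nout) {
      out(oidx, 0) = (i + 1) * h;
      for (int s = 0; s < 7; ++s) out(oidx, s + 1) = y[s];
      out(oidx, 8) = dA; out(oidx, 9) = dB;
      ++oidx;
    }
  }
  return List::create(_["series"] = out, _["h"] = h,
                      _["clipped"] = (double)clipped, _["nout"] = (double)oidx);
}
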