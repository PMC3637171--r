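#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Classic direct-method Gillespie SSA at constant volume. Deliberately
// written as a standalone routine (exponential waiting times, linear
// channel scan) so it can serve as an independent oracle for the
// growth-aware engine in the zero-growth limit. Flat mass-action /
// Michaelis-Menten channels only: no genes, no delays, no division.

// [[Rcpp::export]]
List cpp_classic_ssa(IntegerVector counts0, IntegerVector ord,
                     IntegerVector ri1, IntegerVector ri2,
                     IntegerVector vclass, NumericVector kappa,
                     IntegerVector mm_e, IntegerVector mm_s,
                     NumericVector mm_KmNA, List consume, List release,
                     double V, double t0, double t_end,
                     NumericVector grid) {
  int nsp = counts0.size(), nr = ord.size();
  std::vector<long long> X(nsp);
  for (int s = 0; s < nsp; ++s) X[s] = counts0[s];
  std::vector<std::vector<int>> ci(nr), cn(nr), pi(nr), pn(nr);
  for (int j = 0; j < nr; ++j) {
    List c = consume[j], p = release[j];
    ci[j] = as<std::vector<int>>(c["idx"]);
    cn[j] = as<std::vector<int>>(c["n"]);
    pi[j] = as<std::vector<int>>(p["idx"]);
    pn[j] = as<std::vector<int>>(p["n"]);
  }
  std::vector<double> a(nr);
  int ngrid = grid.size(), gidx = 0;
  IntegerMatrix out(ngrid, nsp);
  auto record_upto = [&](double tnew) {
    while (gidx < ngrid && grid[gidx] <= tnew) {
      for (int s = 0; s < nsp; ++s) out(gidx, s) = (int)X[s];
      ++gidx;
    }
  };

  double t = t0, nev = 0;
  record_upto(t);
  while (t < t_end) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) {
      double p;
      switch (vclass[j]) {
        case 0:
          p = (ord[j] == 0) ? kappa[j] : kappa[j] * X[ri1[j]];
          break;
        case 1:
          p = (ri1[j] == ri2[j])
                  ? kappa[j] * X[ri1[j]] * (X[ri1[j]] - 1.0) / V
                  : kappa[j] * X[ri1[j]] * (double)X[ri2[j]] / V;
          break;
        case 2:
          p = kappa[j] * V;
          break;
        default: {
          double S = (double)X[mm_s[j]];
          p = (S > 0) ? kappa[j] * X[mm_e[j]] * S / (mm_KmNA[j] * V + S) : 0.0;
        }
      }
      a[j] = p > 0 ? p : 0;
      a0 += a[j];
    }
    if (a0 <= 0.0) break;
    double tau = -std::log(unif_rand()) / a0;
    if (t + tau > t_end) { t = t_end; break; }
    t += tau;
    record_upto(t);
    double pick = unif_rand() * a0, cum = 0.0;
    int j = nr - 1;
    for (int q = 0; q < nr; ++q) {
      cum += a[q];
      if (cum >= pick && a[q] > 0) { j = q; break; }
    }
    for (size_t q = 0; q < ci[j].size(); ++q) {
      X[ci[j][q]] -= cn[j][q];
      if (X[ci[j][q]] < 0) stop("classic SSA: negative count");
    }
    for (size_t q = 0; q < pi[j].size(); ++q) X[pi[j][q]] += pn[j][q];
    nev += 1;
  }
  record_upto(t_end);
  return List::create(_["counts"] = out, _["final_counts"] = wrap(X),
                      _["n_events"] = nev);
}
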