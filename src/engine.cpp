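#include <Rcpp.h>
#include <set>
#include <vector>
#include "lambertw.h"

using namespace Rcpp;

double sample_tau(double A, double b, double g, double mu, double r);

// ---------------------------------------------------------------------
// Growth-aware delayed SSA for a single cell cycle.
//
// The cell volume follows V(t) = V_birth * 2^((t - t_birth)/T), so
// mu = ln(2)/T and every inverse-volume propensity decays like
// exp(-mu * s) between events while proportional-volume influxes grow
// like exp(+mu * s); the firing time is sampled exactly from the
// resulting inhomogeneous-Poisson hazard (see sampling.cpp).
//
// Scheduled events (delayed product releases, gene replications) preempt
// the sampled reaction: if one falls inside the sampled waiting interval
// the system advances to it, executes it, and resamples. Ties at one
// timestamp execute delayed releases before replications.
// ---------------------------------------------------------------------

namespace {

struct Ev {
  double time;
  int prio;   // 0 = delayed release, 1 = replication
  long seq;   // FIFO tie-break
  int kind;   // 0 = reaction product release, 1 = transcript release,
              // 2 = replication
  int idx;    // reaction index (kind 0) or gene index (kind 1/2)
};
struct EvLess {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.time != b.time) return a.time < b.time;
    if (a.prio != b.prio) return a.prio < b.prio;
    return a.seq < b.seq;
  }
};

struct CompiledModel {
  int nsp, nr, ng;
  std::vector<int> ord, ri1, ri2, vclass, mm_e, mm_s;
  std::vector<double> kappa, delay, mm_KmNA;
  std::vector<char> noise;
  std::vector<std::vector<int>> cons_idx, cons_n, rel_idx, rel_n;
  std::vector<double> g_a, g_delay;
  std::vector<int> g_mrna;
  std::vector<char> g_noise;
  std::vector<std::vector<int>> s_tf;
  std::vector<std::vector<double>> s_kon, s_koff, s_factor, s_coop;
};

CompiledModel unpack(const List& cm) {
  CompiledModel M;
  M.nsp = as<int>(cm["nsp"]);
  M.nr = as<int>(cm["nr"]);
  M.ng = as<int>(cm["ng"]);
  M.ord = as<std::vector<int>>(cm["ord"]);
  M.ri1 = as<std::vector<int>>(cm["ri1"]);
  M.ri2 = as<std::vector<int>>(cm["ri2"]);
  M.vclass = as<std::vector<int>>(cm["vclass"]);
  M.kappa = as<std::vector<double>>(cm["kappa"]);
  M.delay = as<std::vector<double>>(cm["delay"]);
  M.mm_e = as<std::vector<int>>(cm["mm_e"]);
  M.mm_s = as<std::vector<int>>(cm["mm_s"]);
  M.mm_KmNA = as<std::vector<double>>(cm["mm_KmNA"]);
  LogicalVector nz = cm["noise"];
  for (int j = 0; j < M.nr; ++j) M.noise.push_back(nz[j] ? 1 : 0);
  List cons = cm["consume"], rel = cm["release"];
  for (int j = 0; j < M.nr; ++j) {
    List c = cons[j], r = rel[j];
    M.cons_idx.push_back(as<std::vector<int>>(c["idx"]));
    M.cons_n.push_back(as<std::vector<int>>(c["n"]));
    M.rel_idx.push_back(as<std::vector<int>>(r["idx"]));
    M.rel_n.push_back(as<std::vector<int>>(r["n"]));
  }
  M.g_a = as<std::vector<double>>(cm["g_a"]);
  M.g_delay = as<std::vector<double>>(cm["g_delay"]);
  M.g_mrna = as<std::vector<int>>(cm["g_mrna"]);
  LogicalVector gn = cm["g_noise"];
  for (int k = 0; k < M.ng; ++k) M.g_noise.push_back(gn[k] ? 1 : 0);
  List gs = cm["g_sites"];
  for (int k = 0; k < M.ng; ++k) {
    List s = gs[k];
    M.s_tf.push_back(as<std::vector<int>>(s["tf"]));
    M.s_kon.push_back(as<std::vector<double>>(s["kon"]));
    M.s_koff.push_back(as<std::vector<double>>(s["koff"]));
    M.s_factor.push_back(as<std::vector<double>>(s["factor"]));
    M.s_coop.push_back(as<std::vector<double>>(s["coop"]));
  }
  return M;
}

struct Choice {
  int kind;  // 0 reaction, 1 transcription, 2 bind, 3 unbind
  int rxn, gene, inst, site;
};

struct ChannelScratch {
  std::vector<double> val;
  std::vector<Choice> meta;
  void clear() { val.clear(); meta.clear(); }
  void push(double v, int kind, int rxn, int gene, int inst, int site) {
    val.push_back(v);
    meta.push_back(Choice{kind, rxn, gene, inst, site});
  }
};

double rxn_propensity(const CompiledModel& M, const std::vector<int>& X,
                      double V, double nm, int j) {
  double p = 0.0;
  switch (M.vclass[j]) {
    case 0:  // volume-independent (order 0 or 1)
      p = (M.ord[j] == 0) ? M.kappa[j] : M.kappa[j] * X[M.ri1[j]];
      break;
    case 1: {  // inverse-volume bimolecular
      if (M.ri1[j] == M.ri2[j]) {
        double n = X[M.ri1[j]];
        p = M.kappa[j] * n * (n - 1.0) / V;
      } else {
        p = M.kappa[j] * X[M.ri1[j]] * (double)X[M.ri2[j]] / V;
      }
      break;
    }
    case 2:  // proportional-volume influx
      p = M.kappa[j] * V;
      break;
    case 3: {  // Michaelis-Menten, quasi-static in V between events
      double S = X[M.mm_s[j]], E = X[M.mm_e[j]];
      p = (S > 0.0) ? M.kappa[j] * E * S / (M.mm_KmNA[j] * V + S) : 0.0;
      break;
    }
  }
  if (M.noise[j]) p *= nm;
  return p < 0.0 ? 0.0 : p;
}

typedef std::vector<std::vector<unsigned char>> BoundState;  // per gene: inst*nsites

// One pass over all channels in the fixed enumeration order (reactions,
// then per gene / instance: transcription, then each site's
// bind-or-unbind), accumulating the class totals (A, b, g). When `scr`
// is non-null the per-channel values and identities are also recorded so
// a channel can afterwards be selected from the array without rescanning.
void split_propensities(const CompiledModel& M, const std::vector<int>& X,
                        const BoundState& bound, double V, double nm,
                        double* Aout, double* bout, double* gout,
                        ChannelScratch* scr) {
  double A = 0, b = 0, g = 0;
  if (scr) scr->clear();
  for (int j = 0; j < M.nr; ++j) {
    double p = rxn_propensity(M, X, V, nm, j);
    switch (M.vclass[j]) { case 1: b += p; break; case 2: g += p; break;
                           default: A += p; }
    if (scr) scr->push(p, 0, j, -1, -1, -1);
  }
  for (int k = 0; k < M.ng; ++k) {
    int ns = (int)M.s_tf[k].size();
    int ninst = ns > 0 ? (int)bound[k].size() / ns
                       : (int)bound[k].size();  // ns==0: one slot per inst
    double ak = M.g_a[k] * (M.g_noise[k] ? nm : 1.0);
    for (int i = 0; i < ninst; ++i) {
      int nb = 0;
      double fac = 1.0;
      for (int s = 0; s < ns; ++s)
        if (bound[k][(size_t)i * ns + s]) { ++nb; fac *= M.s_factor[k][s]; }
      double ptx = ak * fac;
      A += ptx;
      if (scr) scr->push(ptx, 1, -1, k, i, -1);
      for (int s = 0; s < ns; ++s) {
        if (bound[k][(size_t)i * ns + s]) {
          double poff = M.s_koff[k][s];
          A += poff;
          if (scr) scr->push(poff, 3, -1, k, i, s);
        } else {
          double coop = (nb < (int)M.s_coop[k].size()) ? M.s_coop[k][nb] : 1.0;
          double pon = M.s_kon[k][s] * coop * X[M.s_tf[k][s]] / V;
          b += pon;
          if (scr) scr->push(pon, 2, -1, k, i, s);
        }
      }
    }
  }
  *Aout = A; *bout = b; *gout = g;
}

// direct-method selection from the recorded channel array
bool pick_channel(const ChannelScratch& scr, double pick, Choice* ch) {
  double cum = 0;
  int last = -1;
  for (size_t q = 0; q < scr.val.size(); ++q) {
    if (scr.val[q] > 0) {
      cum += scr.val[q];
      last = (int)q;
      if (cum >= pick) break;
    }
  }
  if (last < 0) return false;
  *ch = scr.meta[last];
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_cell(List cm, IntegerVector counts0, List bound0, List tag0,
                  double t0, double t_end, double t_birth, double T_s,
                  double V_birth, NumericVector rep_time,
                  IntegerVector rep_gene, NumericVector pend_time,
                  IntegerVector pend_kind, IntegerVector pend_idx,
                  NumericVector grid, double ou_tau, double ou_sigma,
                  double eta0) {
  CompiledModel M = unpack(cm);
  std::vector<int> X = as<std::vector<int>>(counts0);
  if ((int)X.size() != M.nsp) stop("counts length mismatch");
  for (int s = 0; s < M.nsp; ++s)
    if (X[s] < 0) stop("internal-consistency failure: negative count");

  BoundState bound(M.ng);
  std::vector<std::vector<int>> tag(M.ng);
  std::vector<int> ninst(M.ng);
  for (int k = 0; k < M.ng; ++k) {
    IntegerMatrix bm = bound0[k];
    int ni = bm.nrow();
    int ns = (int)M.s_tf[k].size();
    if (ns > 0 && bm.ncol() != ns) stop("bound-state column mismatch");
    ninst[k] = ni;
    bound[k].assign((size_t)ni * std::max(ns, 1), 0);
    if (ns > 0)
      for (int i = 0; i < ni; ++i)
        for (int s = 0; s < ns; ++s)
          bound[k][(size_t)i * ns + s] = (unsigned char)(bm(i, s) != 0);
    tag[k] = as<std::vector<int>>(tag0[k]);
    if ((int)tag[k].size() != ni) stop("tag length mismatch");
  }

  double mu = std::log(2.0) / T_s;
  bool ou_active = (ou_sigma > 0.0) || (eta0 != 0.0);
  double eta = eta0;

  std::multiset<Ev, EvLess> queue;
  long seq = 0;
  for (int i = 0; i < pend_time.size(); ++i)
    queue.insert(Ev{pend_time[i], 0, seq++, pend_kind[i], pend_idx[i]});
  for (int i = 0; i < rep_time.size(); ++i)
    queue.insert(Ev{rep_time[i], 1, seq++, 2, rep_gene[i]});

  int ngrid = grid.size();
  IntegerMatrix out_counts(ngrid, M.nsp);
  IntegerMatrix out_copies(ngrid, M.ng);
  int gidx = 0;
  auto record_upto = [&](double tnew) {
    while (gidx < ngrid && grid[gidx] <= tnew) {
      for (int s = 0; s < M.nsp; ++s) out_counts(gidx, s) = X[s];
      for (int k = 0; k < M.ng; ++k) out_copies(gidx, k) = ninst[k];
      ++gidx;
    }
  };
  auto volume_at = [&](double t) {
    return V_birth * std::exp(mu * (t - t_birth));
  };
  auto ou_update = [&](double dt) {
    if (!ou_active || dt <= 0.0) {
      if (ou_active && ou_sigma > 0.0 && dt == 0.0) {}
      return;
    }
    double decay = std::exp(-dt / ou_tau);
    eta *= decay;
    if (ou_sigma > 0.0)
      eta += ou_sigma * std::sqrt(-std::expm1(-2.0 * dt / ou_tau)) *
             norm_rand();
  };
  auto apply_delta = [&](const std::vector<int>& idx,
                         const std::vector<int>& n, int sign) {
    for (size_t q = 0; q < idx.size(); ++q) {
      X[idx[q]] += sign * n[q];
      if (X[idx[q]] < 0)
        stop("internal error: reactant count went negative");
    }
  };
  auto do_replicate = [&](int k) {
    int ns = (int)M.s_tf[k].size();
    int ni = ninst[k];
    if (ns > 0) {
      for (int i = 0; i < ni; ++i)
        for (int s = 0; s < ns; ++s)
          if (bound[k][(size_t)i * ns + s]) {   // fork displaces bound TFs
            X[M.s_tf[k][s]] += 1;
            bound[k][(size_t)i * ns + s] = 0;
          }
    }
    bound[k].assign((size_t)(2 * ni) * std::max(ns, 1), 0);
    tag[k].assign(ni, 1);
    tag[k].resize((size_t)2 * ni, 2);  // new sister copies tagged 2
    ninst[k] = 2 * ni;
  };

  double t = t0;
  record_upto(t);
  double nev = 0;
  long long guard = 0;
  ChannelScratch scr;
  while (t < t_end) {
    if (++guard > 2000000000LL) stop("event-count guard tripped");
    double A, b, g;
    Choice ch;
    split_propensities(M, X, bound, volume_at(t), std::exp(eta), &A, &b, &g,
                       nullptr);
    double r1 = unif_rand();
    double tau = sample_tau(A, b, g, mu, r1);
    double t_cand = R_FINITE(tau) ? t + tau : R_PosInf;

    bool have_ev = !queue.empty() && queue.begin()->time <= t_end;
    if (have_ev && queue.begin()->time <= t_cand) {
      Ev ev = *queue.begin();
      queue.erase(queue.begin());
      if (ev.time < t) stop("scheduled event in the past");
      record_upto(ev.time);
      ou_update(ev.time - t);
      t = ev.time;
      if (ev.kind == 0) {
        apply_delta(M.rel_idx[ev.idx], M.rel_n[ev.idx], +1);
      } else if (ev.kind == 1) {
        X[M.g_mrna[ev.idx]] += 1;
      } else {
        do_replicate(ev.idx);
      }
      continue;  // resample: no reaction fires inside the interval
    }
    if (t_cand > t_end) {
      record_upto(t_end);
      ou_update(t_end - t);
      t = t_end;
      break;
    }
    // fire the sampled channel at t_cand
    record_upto(t_cand);
    double dt = t_cand - t;
    t = t_cand;
    double Vf = volume_at(t);
    double A2, b2, g2;
    split_propensities(M, X, bound, Vf, std::exp(eta), &A2, &b2, &g2, &scr);
    double tot = A2 + b2 + g2;
    double r2 = unif_rand();
    if (tot > 0.0 && pick_channel(scr, r2 * tot, &ch)) {
      switch (ch.kind) {
        case 0: {
          int j = ch.rxn;
          apply_delta(M.cons_idx[j], M.cons_n[j], -1);
          if (M.delay[j] > 0.0)
            queue.insert(Ev{t + M.delay[j], 0, seq++, 0, j});
          else
            apply_delta(M.rel_idx[j], M.rel_n[j], +1);
          break;
        }
        case 1: {
          int k = ch.gene;
          if (M.g_delay[k] > 0.0)
            queue.insert(Ev{t + M.g_delay[k], 0, seq++, 1, k});
          else
            X[M.g_mrna[k]] += 1;
          break;
        }
        case 2: {
          int k = ch.gene, ns = (int)M.s_tf[k].size();
          int tf = M.s_tf[k][ch.site];
          if (X[tf] <= 0) stop("internal error: binding with no free TF");
          X[tf] -= 1;
          bound[k][(size_t)ch.inst * ns + ch.site] = 1;
          break;
        }
        case 3: {
          int k = ch.gene, ns = (int)M.s_tf[k].size();
          bound[k][(size_t)ch.inst * ns + ch.site] = 0;
          X[M.s_tf[k][ch.site]] += 1;
          break;
        }
      }
      nev += 1;
    }
    ou_update(dt);
  }
  // events scheduled exactly at the stopping time: the loop exits when t
  // reaches t_end, so drain the remainder here (e.g. a second gene whose
  // replication coincides with division)
  while (!queue.empty() && queue.begin()->time <= t_end) {
    Ev ev = *queue.begin();
    queue.erase(queue.begin());
    if (ev.kind == 0) apply_delta(M.rel_idx[ev.idx], M.rel_n[ev.idx], +1);
    else if (ev.kind == 1) X[M.g_mrna[ev.idx]] += 1;
    else do_replicate(ev.idx);
  }
  record_upto(t_end);

  List fb(M.ng), ft(M.ng);
  for (int k = 0; k < M.ng; ++k) {
    int ns = (int)M.s_tf[k].size();
    IntegerMatrix bm(ninst[k], ns);
    for (int i = 0; i < ninst[k]; ++i)
      for (int s = 0; s < ns; ++s)
        bm(i, s) = bound[k][(size_t)i * ns + s];
    fb[k] = bm;
    ft[k] = wrap(tag[k]);
  }
  std::vector<double> qt; std::vector<int> qk, qi;
  for (const Ev& ev : queue)
    if (ev.kind != 2) { qt.push_back(ev.time); qk.push_back(ev.kind);
                        qi.push_back(ev.idx); }
  return List::create(
      _["counts"] = out_counts, _["copies"] = out_copies,
      _["final_counts"] = wrap(X), _["final_bound"] = fb,
      _["final_tag"] = ft, _["pend_time"] = wrap(qt),
      _["pend_kind"] = wrap(qk), _["pend_idx"] = wrap(qi),
      _["n_events"] = nev, _["eta"] = eta);
}
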