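// Simulation cores: exact Gillespie (direct method) and the adaptive-step
// burst Langevin integrator, for a single gene and for a two-gene
// Hill-regulated network. All randomness comes from R's RNG (set.seed at the
// R level makes every run reproducible). Trajectories are recorded on a
// sample grid (last-event hold); long-run stationary statistics are
// accumulated as exact time integrals with batch means for standard errors.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline long long iround(double x) { return (long long)::llround(x); }

// record states on an ascending sample grid; state at grid time s is the
// state after the last event at or before s
struct Recorder {
  const NumericVector& grid;
  NumericMatrix out;
  R_xlen_t gi;
  int nspec;
  Recorder(const NumericVector& g, int ns)
    : grid(g), out(g.size(), ns), gi(0), nspec(ns) {}
  void until(double t_new, const double* st) {
    while (gi < grid.size() && grid[gi] < t_new) {
      for (int k = 0; k < nspec; ++k) out(gi, k) = st[k];
      ++gi;
    }
  }
  void finish(const double* st) { until(R_PosInf, st); }
};

// exact time integrals of state and state^2 over [t0, t1], split into
// batches for batch-mean standard errors
struct TimeAvg {
  bool on;
  double t0, t1, blen;
  int nb, nspec;
  NumericMatrix s1, s2;
  TimeAvg(double burn, double tend, int nbatch, int ns)
    : on(nbatch > 0 && tend > burn),
      t0(burn), t1(tend),
      nb(nbatch > 0 ? nbatch : 1), nspec(ns),
      blen(on ? (tend - burn) / (nbatch > 0 ? nbatch : 1) : 1.0),
      s1(nb, ns), s2(nb, ns) {}
  void add(double ta, double tb, const double* v) {
    if (!on) return;
    double lo = std::max(ta, t0), hi = std::min(tb, t1);
    while (lo < hi) {
      int b = (int)((lo - t0) / blen);
      if (b >= nb) b = nb - 1;
      double up = std::min(hi, t0 + (b + 1) * blen);
      double seg = up - lo;
      if (seg <= 0) break;
      for (int k = 0; k < nspec; ++k) {
        s1(b, k) += v[k] * seg;
        s2(b, k) += v[k] * v[k] * seg;
      }
      lo = up;
    }
  }
};

inline double hill_frac(double p1, double K, double nH) {
  if (nH == 0.0) return 0.5;
  if (p1 <= 0.0) return nH > 0 ? 1.0 : 0.0;
  double x = p1 / K, r;
  int k = (int)nH;
  if (nH == (double)k && k > -9 && k < 9) { // integer Hill coefficients
    r = 1.0;                                // (hot path: avoid pow)
    int a = k > 0 ? k : -k;
    while (a-- > 0) r *= x;
    if (k < 0) r = 1.0 / r;
  } else {
    r = std::pow(x, nH);
  }
  return 1.0 / (1.0 + r);
}

// step bound for a burst production channel: max(eps*y, max(bbar,1)) / rate
inline double tau_burst_bound(double eps, double y, double bbar, double rprod) {
  if (rprod <= 0.0) return R_PosInf;
  return std::max(eps * y, std::max(bbar, 1.0)) / rprod;
}

// tau-leaping bound (mean and variance) for plain chemical-Langevin channels
inline double tau_cle_bound(double eps, double y, double mean_rate,
                            double var_rate) {
  double num = std::max(eps * y, 1.0);
  double b1 = std::fabs(mean_rate) > 0 ? num / std::fabs(mean_rate) : R_PosInf;
  double b2 = var_rate > 0 ? num * num / var_rate : R_PosInf;
  return std::min(b1, b2);
}

struct Prod {
  long long raw, applied, newdef;
};

// Gaussian production draw, rounded half-away-from-zero, passed through the
// negative-production accumulator (deficit <= 0)
inline Prod draw_prod(double delta, double var, long long def) {
  double x = delta + std::sqrt(var) * ::norm_rand();
  long long raw = iround(x);
  long long tot = raw + def;
  Prod pr;
  pr.raw = raw;
  pr.applied = tot > 0 ? tot : 0;
  pr.newdef = tot > 0 ? 0 : tot;
  return pr;
}

inline long long draw_deg(double mu) {
  if (mu <= 0) return 0;
  return iround(mu + std::sqrt(mu) * ::norm_rand());
}

} // namespace

// ---------------------------------------------------------------------------
// Exact SSA, single gene: channels are gene activation/deactivation,
// transcription, mRNA degradation, translation, protein degradation.
// kg_times/kg_values give an optional piecewise-constant activation schedule.
// [[Rcpp::export]]
List ssa_run_cpp(NumericVector r, int ncop, NumericVector init, double t_end,
                 NumericVector grid, NumericVector kg_times,
                 NumericVector kg_values, double t_burn, int n_batch) {
  double gg = r[1], km = r[2], gm = r[3], kp = r[4], gp = r[5];
  long long g = (long long)init[0], m = (long long)init[1],
            p = (long long)init[2];
  bool sched = kg_times.size() > 0;
  R_xlen_t sidx = 0;
  double kg = sched ? kg_values[0] : r[0];
  double t = 0.0;
  long long nev = 0;
  Recorder rec(grid, 3);
  TimeAvg ta(t_burn, t_end, n_batch, 2); // (m, p)
  double st[3], av[2];

  while (t < t_end) {
    double next_break =
        (sched && sidx < kg_times.size()) ? kg_times[sidx] : R_PosInf;
    double a1 = kg * (ncop - g), a2 = gg * g, a3 = km * g, a4 = gm * m,
           a5 = kp * m, a6 = gp * p;
    double a0 = a1 + a2 + a3 + a4 + a5 + a6;
    double t_new = a0 > 0 ? t + ::exp_rand() / a0 : R_PosInf;
    st[0] = (double)g; st[1] = (double)m; st[2] = (double)p;
    av[0] = st[1]; av[1] = st[2];
    if (t_new >= next_break && next_break <= t_end) {
      rec.until(next_break, st);
      ta.add(t, next_break, av);
      t = next_break;
      ++sidx;
      kg = kg_values[sidx];
      continue; // memoryless: re-draw with the new propensities
    }
    if (t_new > t_end) {
      rec.until(t_end, st);
      ta.add(t, t_end, av);
      t = t_end;
      break;
    }
    rec.until(t_new, st);
    ta.add(t, t_new, av);
    double u = ::unif_rand() * a0;
    if ((u -= a1) < 0) ++g;
    else if ((u -= a2) < 0) --g;
    else if ((u -= a3) < 0) ++m;
    else if ((u -= a4) < 0) --m;
    else if ((u -= a5) < 0) ++p;
    else --p;
    t = t_new;
    ++nev;
  }
  st[0] = (double)g; st[1] = (double)m; st[2] = (double)p;
  rec.finish(st);
  return List::create(
      _["states"] = rec.out,
      _["final"] = NumericVector::create((double)g, (double)m, (double)p),
      _["n_events"] = (double)nev, _["ta_s1"] = ta.s1, _["ta_s2"] = ta.s2,
      _["ta_time"] = ta.on ? (ta.t1 - ta.t0) : 0.0);
}

// ---------------------------------------------------------------------------
// Exact SSA, two-gene repression network (12 channels). Downstream
// transcription propensity: g2 * (km2 * Hill(p1) + kl).
// [[Rcpp::export]]
List ssa_net_run_cpp(NumericVector up, NumericVector dn, double K, double nH,
                     double kl, int ncop1, int ncop2, NumericVector init,
                     double t_end, NumericVector grid, double t_burn,
                     int n_batch) {
  double kg1 = up[0], gg1 = up[1], km1 = up[2], gm1 = up[3], kp1 = up[4],
         gp1 = up[5];
  double kg2 = dn[0], gg2 = dn[1], km2 = dn[2], gm2 = dn[3], kp2 = dn[4],
         gp2 = dn[5];
  long long s[6]; // g1, m1, p1, g2, m2, p2
  for (int k = 0; k < 6; ++k) s[k] = (long long)init[k];
  double t = 0.0;
  long long nev = 0;
  Recorder rec(grid, 6);
  TimeAvg ta(t_burn, t_end, n_batch, 2); // (p1, p2)
  double st[6], av[2];

  while (t < t_end) {
    double a[12];
    a[0] = kg1 * (ncop1 - s[0]);
    a[1] = gg1 * s[0];
    a[2] = km1 * s[0];
    a[3] = gm1 * s[1];
    a[4] = kp1 * s[1];
    a[5] = gp1 * s[2];
    a[6] = kg2 * (ncop2 - s[3]);
    a[7] = gg2 * s[3];
    a[8] = (km2 * hill_frac((double)s[2], K, nH) + kl) * s[3];
    a[9] = gm2 * s[4];
    a[10] = kp2 * s[4];
    a[11] = gp2 * s[5];
    double a0 = 0;
    for (int k = 0; k < 12; ++k) a0 += a[k];
    double t_new = a0 > 0 ? t + ::exp_rand() / a0 : R_PosInf;
    for (int k = 0; k < 6; ++k) st[k] = (double)s[k];
    av[0] = st[2]; av[1] = st[5];
    if (t_new > t_end) {
      rec.until(t_end, st);
      ta.add(t, t_end, av);
      t = t_end;
      break;
    }
    rec.until(t_new, st);
    ta.add(t, t_new, av);
    double u = ::unif_rand() * a0;
    int ch = 0;
    while (ch < 11 && (u -= a[ch]) >= 0) ++ch;
    switch (ch) {
      case 0: ++s[0]; break; case 1: --s[0]; break;
      case 2: ++s[1]; break; case 3: --s[1]; break;
      case 4: ++s[2]; break; case 5: --s[2]; break;
      case 6: ++s[3]; break; case 7: --s[3]; break;
      case 8: ++s[4]; break; case 9: --s[4]; break;
      case 10: ++s[5]; break; case 11: --s[5]; break;
    }
    t = t_new;
    ++nev;
  }
  for (int k = 0; k < 6; ++k) st[k] = (double)s[k];
  rec.finish(st);
  NumericVector fin(6);
  for (int k = 0; k < 6; ++k) fin[k] = (double)s[k];
  return List::create(_["states"] = rec.out, _["final"] = fin,
                      _["n_events"] = (double)nev, _["ta_s1"] = ta.s1,
                      _["ta_s2"] = ta.s2,
                      _["ta_time"] = ta.on ? (ta.t1 - ta.t0) : 0.0);
}

// ---------------------------------------------------------------------------
// Burst Langevin integrator, single gene.
// regime: 1 = MRNA_BURST (tracks m, p), 2 = BOTH_BURSTS (tracks p),
//         3 = PROTEIN_BURST (tracks g, p), 4 = NO_BURST (tracks g, m, p).
// Gene switching channels are always critical; degradation channels become
// critical below ncrit copies. When tau_c < tau the non-critical channels
// are propagated over tau_c and the sampled critical event fires. Gaussian
// production draws are rounded and pass through a per-species
// negative-production accumulator; a provisionally negative count triggers
// the half-tau retry (the critical event, not yet due, is dropped).
// Draw order per attempt: m production, m degradation, p production,
// p degradation (zero-rate channels consume no draws).
// [[Rcpp::export]]
List bl_run_cpp(int regime, NumericVector r, int ncop, NumericVector init,
                double t_end, double eps, int ncrit, int max_halv,
                NumericVector grid, NumericVector kg_times,
                NumericVector kg_values, double t_burn, int n_batch) {
  double gg = r[1], km = r[2], gm = r[3], kp = r[4], gp = r[5];
  bool sched = kg_times.size() > 0;
  R_xlen_t sidx = 0;
  double kg = sched ? kg_values[0] : r[0];
  bool tr_g = (regime == 3 || regime == 4);
  bool tr_m = (regime == 1 || regime == 4);
  long long g = (long long)init[0], m = (long long)init[1],
            p = (long long)init[2];
  long long def_m = 0, def_p = 0;
  long long raw_m = 0, app_m = 0, raw_p = 0, app_p = 0;
  long long nsteps = 0, nhalv = 0, ncritev = 0;
  double t = 0.0;
  Recorder rec(grid, 3);
  TimeAvg ta(t_burn, t_end, n_batch, 2); // (m, p)
  double st[3], av[2];
  double bp = kp / gm;

  while (t < t_end - 1e-12 * std::max(1.0, t_end)) {
    while (sched && sidx < kg_times.size() &&
           t >= kg_times[sidx] - 1e-12 * std::max(1.0, t_end)) {
      ++sidx;
      kg = sidx < kg_values.size() ? kg_values[sidx] : kg;
    }
    double next_break =
        (sched && sidx < kg_times.size()) ? kg_times[sidx] : R_PosInf;
    double bm = km / (kg + gg);
    double remaining = std::min(t_end, next_break) - t;

    // burst / CLE production rates for this regime
    double rprod_m = 0, varr_m = 0; // mRNA production: mean and var rate
    double rprod_p = 0, varr_p = 0; // protein production
    bool m_deg_crit = tr_m && m > 0 && m < ncrit;
    bool p_deg_crit = p > 0 && p < ncrit;
    double tau = remaining;
    if (regime == 1) {
      double re = (double)ncop * kg; // mRNA burst events
      rprod_m = re * bm;
      varr_m = re * bm * (2 * bm + 1);
      rprod_p = kp * (double)m; // plain CLE translation
      varr_p = rprod_p;
      tau = std::min(tau, tau_burst_bound(eps, (double)m, bm, rprod_m));
      if (!m_deg_crit && m > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)m, gm * (double)m,
                                          gm * (double)m));
      double pdeg = p_deg_crit ? 0.0 : gp * (double)p;
      if (rprod_p > 0 || pdeg > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)p, rprod_p - pdeg,
                                          rprod_p + pdeg));
    } else if (regime == 2) {
      double re = (double)ncop * kg * bm; // protein burst events
      rprod_p = re * bp;
      varr_p = re * bp * (2 * bm * bp + 2 * bp + 1);
      tau = std::min(tau, tau_burst_bound(eps, (double)p, bp, rprod_p));
      if (!p_deg_crit && p > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)p, gp * (double)p,
                                          gp * (double)p));
    } else if (regime == 3) {
      double re = (double)g * km; // protein burst events while gene active
      rprod_p = re * bp;
      varr_p = re * bp * (2 * bp + 1);
      tau = std::min(tau, tau_burst_bound(eps, (double)p, bp, rprod_p));
      if (!p_deg_crit && p > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)p, gp * (double)p,
                                          gp * (double)p));
      tau = std::min(tau, 0.1 / std::max(kg, gg)); // g constant within tau
    } else { // regime 4: plain CLE on m and p, gene as events
      rprod_m = km * (double)g;
      varr_m = rprod_m;
      rprod_p = kp * (double)m;
      varr_p = rprod_p;
      double mdeg = m_deg_crit ? 0.0 : gm * (double)m;
      if (rprod_m > 0 || mdeg > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)m, rprod_m - mdeg,
                                          rprod_m + mdeg));
      double pdeg = p_deg_crit ? 0.0 : gp * (double)p;
      if (rprod_p > 0 || pdeg > 0)
        tau = std::min(tau, tau_cle_bound(eps, (double)p, rprod_p - pdeg,
                                          rprod_p + pdeg));
      tau = std::min(tau, 0.1 / std::max(kg, gg));
    }

    // critical channels: gene switching (regimes 3, 4) and low-copy
    // degradations; codes 0 g+, 1 g-, 2 m-, 3 p-
    double ac[4] = {0, 0, 0, 0};
    if (tr_g) {
      ac[0] = kg * (double)(ncop - g);
      ac[1] = gg * (double)g;
    }
    if (m_deg_crit) ac[2] = gm * (double)m;
    if (p_deg_crit) ac[3] = gp * (double)p;
    double acrit = ac[0] + ac[1] + ac[2] + ac[3];
    int crit_ch = -1;
    double tau_use = tau;
    if (acrit > 0) {
      double tc = ::exp_rand() / acrit;
      if (tc < tau) {
        tau_use = tc;
        double u = ::unif_rand() * acrit;
        crit_ch = 0;
        while (crit_ch < 3 && (u -= ac[crit_ch]) >= 0) ++crit_ch;
      }
    }

    long long halv = 0;
    for (;;) {
      Prod pm = {0, 0, def_m}, pp = {0, 0, def_p};
      long long dm_ = 0, dp_ = 0;
      if (tr_m && rprod_m > 0)
        pm = draw_prod(rprod_m * tau_use, varr_m * tau_use, def_m);
      if (tr_m && !m_deg_crit && m > 0) dm_ = draw_deg(gm * (double)m * tau_use);
      if (rprod_p > 0)
        pp = draw_prod(rprod_p * tau_use, varr_p * tau_use, def_p);
      if (!p_deg_crit && p > 0) dp_ = draw_deg(gp * (double)p * tau_use);
      long long g_new = g, m_new = m + pm.applied - dm_,
                p_new = p + pp.applied - dp_;
      if (crit_ch == 0) ++g_new;
      else if (crit_ch == 1) --g_new;
      else if (crit_ch == 2) --m_new;
      else if (crit_ch == 3) --p_new;
      if (m_new >= 0 && p_new >= 0) {
        raw_m += pm.raw; app_m += pm.applied; def_m = pm.newdef;
        raw_p += pp.raw; app_p += pp.applied; def_p = pp.newdef;
        st[0] = (double)g; st[1] = (double)m; st[2] = (double)p;
        av[0] = st[1]; av[1] = st[2];
        rec.until(t + tau_use, st);
        ta.add(t, t + tau_use, av);
        g = g_new; m = m_new; p = p_new;
        t += tau_use;
        ++nsteps;
        if (crit_ch >= 0) ++ncritev;
        break;
      }
      if (++halv > max_halv)
        stop("burst Langevin step: count still negative after %d halvings "
             "(t = %g, m = %d, p = %d)",
             max_halv, t, (int)m, (int)p);
      ++nhalv;
      tau_use *= 0.5;
      crit_ch = -1; // critical event no longer due within tau_use
    }
  }
  st[0] = (double)g; st[1] = (double)m; st[2] = (double)p;
  rec.finish(st);
  return List::create(
      _["states"] = rec.out,
      _["final"] = NumericVector::create((double)g, (double)m, (double)p),
      _["n_steps"] = (double)nsteps, _["n_halvings"] = (double)nhalv,
      _["n_critical_events"] = (double)ncritev,
      _["raw_production"] = NumericVector::create((double)raw_m, (double)raw_p),
      _["applied_production"] =
          NumericVector::create((double)app_m, (double)app_p),
      _["deficit"] = NumericVector::create((double)def_m, (double)def_p),
      _["ta_s1"] = ta.s1, _["ta_s2"] = ta.s2,
      _["ta_time"] = ta.on ? (ta.t1 - ta.t0) : 0.0);
}

// ---------------------------------------------------------------------------
// Burst Langevin, two-gene repression network. Both genes run in
// both-bursts mode (only p1 and p2 are tracked); the downstream effective
// mRNA burst size (km2 * Hill(p1) + kl) / (kg2 + gg2) is recomputed every
// step from the current p1, which is treated as constant within the step.
// [[Rcpp::export]]
List bl_net_run_cpp(NumericVector up, NumericVector dn, double K, double nH,
                    double kl, int ncop1, int ncop2, NumericVector init,
                    double t_end, double eps, int ncrit, int max_halv,
                    NumericVector grid, double t_burn, int n_batch) {
  double kg1 = up[0], gg1 = up[1], km1 = up[2], gm1 = up[3], kp1 = up[4],
         gp1 = up[5];
  double kg2 = dn[0], gg2 = dn[1], km2 = dn[2], gm2 = dn[3], kp2 = dn[4],
         gp2 = dn[5];
  double bm1 = km1 / (kg1 + gg1), bp1 = kp1 / gm1, bp2 = kp2 / gm2;
  long long p1 = (long long)init[0], p2 = (long long)init[1];
  long long def1 = 0, def2 = 0;
  long long raw1 = 0, app1 = 0, raw2 = 0, app2 = 0;
  long long nsteps = 0, nhalv = 0, ncritev = 0;
  double t = 0.0;
  Recorder rec(grid, 2);
  TimeAvg ta(t_burn, t_end, n_batch, 2);
  double st[2];

  while (t < t_end - 1e-12 * std::max(1.0, t_end)) {
    double remaining = t_end - t;
    double re1 = (double)ncop1 * kg1 * bm1;
    double rp1 = re1 * bp1;
    double v1 = re1 * bp1 * (2 * bm1 * bp1 + 2 * bp1 + 1);
    double bm2 = (km2 * hill_frac((double)p1, K, nH) + kl) / (kg2 + gg2);
    double re2 = (double)ncop2 * kg2 * bm2;
    double rp2 = re2 * bp2;
    double v2 = re2 * bp2 * (2 * bm2 * bp2 + 2 * bp2 + 1);
    bool c1 = p1 > 0 && p1 < ncrit;
    bool c2 = p2 > 0 && p2 < ncrit;
    double tau = remaining;
    tau = std::min(tau, tau_burst_bound(eps, (double)p1, bp1, rp1));
    if (!c1 && p1 > 0)
      tau = std::min(tau, tau_cle_bound(eps, (double)p1, gp1 * (double)p1,
                                        gp1 * (double)p1));
    tau = std::min(tau, tau_burst_bound(eps, (double)p2, bp2, rp2));
    if (!c2 && p2 > 0)
      tau = std::min(tau, tau_cle_bound(eps, (double)p2, gp2 * (double)p2,
                                        gp2 * (double)p2));
    double ac[2] = {c1 ? gp1 * (double)p1 : 0.0, c2 ? gp2 * (double)p2 : 0.0};
    double acrit = ac[0] + ac[1];
    int crit_ch = -1;
    double tau_use = tau;
    if (acrit > 0) {
      double tc = ::exp_rand() / acrit;
      if (tc < tau) {
        tau_use = tc;
        crit_ch = (::unif_rand() * acrit < ac[0]) ? 0 : 1;
      }
    }
    long long halv = 0;
    for (;;) {
      Prod q1 = {0, 0, def1}, q2 = {0, 0, def2};
      long long d1 = 0, d2 = 0;
      if (rp1 > 0) q1 = draw_prod(rp1 * tau_use, v1 * tau_use, def1);
      if (!c1 && p1 > 0) d1 = draw_deg(gp1 * (double)p1 * tau_use);
      if (rp2 > 0) q2 = draw_prod(rp2 * tau_use, v2 * tau_use, def2);
      if (!c2 && p2 > 0) d2 = draw_deg(gp2 * (double)p2 * tau_use);
      long long p1n = p1 + q1.applied - d1 - (crit_ch == 0 ? 1 : 0);
      long long p2n = p2 + q2.applied - d2 - (crit_ch == 1 ? 1 : 0);
      if (p1n >= 0 && p2n >= 0) {
        raw1 += q1.raw; app1 += q1.applied; def1 = q1.newdef;
        raw2 += q2.raw; app2 += q2.applied; def2 = q2.newdef;
        st[0] = (double)p1; st[1] = (double)p2;
        rec.until(t + tau_use, st);
        ta.add(t, t + tau_use, st);
        p1 = p1n; p2 = p2n;
        t += tau_use;
        ++nsteps;
        if (crit_ch >= 0) ++ncritev;
        break;
      }
      if (++halv > max_halv)
        stop("network burst Langevin step: count still negative after %d "
             "halvings (t = %g)", max_halv, t);
      ++nhalv;
      tau_use *= 0.5;
      crit_ch = -1;
    }
  }
  st[0] = (double)p1; st[1] = (double)p2;
  rec.finish(st);
  return List::create(
      _["states"] = rec.out,
      _["final"] = NumericVector::create((double)p1, (double)p2),
      _["n_steps"] = (double)nsteps, _["n_halvings"] = (double)nhalv,
      _["n_critical_events"] = (double)ncritev,
      _["raw_production"] = NumericVector::create((double)raw1, (double)raw2),
      _["applied_production"] =
          NumericVector::create((double)app1, (double)app2),
      _["deficit"] = NumericVector::create((double)def1, (double)def2),
      _["ta_s1"] = ta.s1, _["ta_s2"] = ta.s2,
      _["ta_time"] = ta.on ? (ta.t1 - ta.t0) : 0.0);
}
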