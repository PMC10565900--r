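// Core numerical engine: competitive Lotka-Volterra growth of a cooperator
// and a cheat strain, serial-passage cycling, and the individual-based
// metapopulation life cycle. Integration is Dormand-Prince RK5(4) with
// adaptive step control (no ODE solver package is assumed).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ModelP {
  double r, K, alpha, h, a, b, s_d, t_d, s_f, t_f;
};

ModelP as_modelp(const List& p) {
  ModelP m;
  m.r = as<double>(p["r"]);
  m.K = as<double>(p["K"]);
  m.alpha = as<double>(p["alpha"]);
  m.h = as<double>(p["h"]);
  m.a = as<double>(p["a"]);
  m.b = as<double>(p["b"]);
  m.s_d = as<double>(p["s_d"]);
  m.t_d = as<double>(p["t_d"]);
  m.s_f = as<double>(p["s_f"]);
  m.t_f = as<double>(p["t_f"]);
  return m;
}

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// dN_co/dt and dN_ch/dt; both zero for an empty population (the cheat
// frequency term is then left unevaluated by contract).
inline void derivs(double co, double ch, const ModelP& p,
                   double& dco, double& dch) {
  double tot = co + ch;
  if (tot <= 0.0) { dco = 0.0; dch = 0.0; return; }
  dco = p.r * co * (1.0 - (co + p.alpha * ch) / p.K);
  if (ch <= 0.0) { dch = 0.0; return; }
  double dm = 1.0 - p.a + p.a * logistic(p.s_d * (co - p.t_d));
  double fm = 1.0 - p.b + p.b * logistic(p.s_f * (co / tot - p.t_f));
  dch = dm * fm * p.h * p.r * ch * (1.0 - (p.alpha * co + ch) / p.K);
}

const double DENSITY_FLOOR = 1e-12;

// Advance (co, ch) by tspan with Dormand-Prince 5(4) adaptive stepping.
// h_next carries the step-size hint across calls so dense output stays cheap.
void advance(double& co, double& ch, const ModelP& p, double tspan,
             double rtol, double atol, double& h_next) {
  if (tspan <= 0.0) return;
  double t = 0.0;
  double h = (h_next > 0.0) ? std::min(h_next, tspan) : tspan / 100.0;
  long n_steps = 0;
  while (t < tspan) {
    if (h > tspan - t) h = tspan - t;
    double k1co, k1ch, k2co, k2ch, k3co, k3ch, k4co, k4ch,
           k5co, k5ch, k6co, k6ch, k7co, k7ch;
    derivs(co, ch, p, k1co, k1ch);
    derivs(co + h * (1.0 / 5.0) * k1co,
           ch + h * (1.0 / 5.0) * k1ch, p, k2co, k2ch);
    derivs(co + h * (3.0 / 40.0 * k1co + 9.0 / 40.0 * k2co),
           ch + h * (3.0 / 40.0 * k1ch + 9.0 / 40.0 * k2ch), p, k3co, k3ch);
    derivs(co + h * (44.0 / 45.0 * k1co - 56.0 / 15.0 * k2co + 32.0 / 9.0 * k3co),
           ch + h * (44.0 / 45.0 * k1ch - 56.0 / 15.0 * k2ch + 32.0 / 9.0 * k3ch),
           p, k4co, k4ch);
    derivs(co + h * (19372.0 / 6561.0 * k1co - 25360.0 / 2187.0 * k2co +
                     64448.0 / 6561.0 * k3co - 212.0 / 729.0 * k4co),
           ch + h * (19372.0 / 6561.0 * k1ch - 25360.0 / 2187.0 * k2ch +
                     64448.0 / 6561.0 * k3ch - 212.0 / 729.0 * k4ch),
           p, k5co, k5ch);
    derivs(co + h * (9017.0 / 3168.0 * k1co - 355.0 / 33.0 * k2co +
                     46732.0 / 5247.0 * k3co + 49.0 / 176.0 * k4co -
                     5103.0 / 18656.0 * k5co),
           ch + h * (9017.0 / 3168.0 * k1ch - 355.0 / 33.0 * k2ch +
                     46732.0 / 5247.0 * k3ch + 49.0 / 176.0 * k4ch -
                     5103.0 / 18656.0 * k5ch),
           p, k6co, k6ch);
    double co5 = co + h * (35.0 / 384.0 * k1co + 500.0 / 1113.0 * k3co +
                           125.0 / 192.0 * k4co - 2187.0 / 6784.0 * k5co +
                           11.0 / 84.0 * k6co);
    double ch5 = ch + h * (35.0 / 384.0 * k1ch + 500.0 / 1113.0 * k3ch +
                           125.0 / 192.0 * k4ch - 2187.0 / 6784.0 * k5ch +
                           11.0 / 84.0 * k6ch);
    derivs(co5, ch5, p, k7co, k7ch);
    double co4 = co + h * (5179.0 / 57600.0 * k1co + 7571.0 / 16695.0 * k3co +
                           393.0 / 640.0 * k4co - 92097.0 / 339200.0 * k5co +
                           187.0 / 2100.0 * k6co + 1.0 / 40.0 * k7co);
    double ch4 = ch + h * (5179.0 / 57600.0 * k1ch + 7571.0 / 16695.0 * k3ch +
                           393.0 / 640.0 * k4ch - 92097.0 / 339200.0 * k5ch +
                           187.0 / 2100.0 * k6ch + 1.0 / 40.0 * k7ch);
    double sc_co = atol + rtol * std::max(std::fabs(co), std::fabs(co5));
    double sc_ch = atol + rtol * std::max(std::fabs(ch), std::fabs(ch5));
    double e_co = (co5 - co4) / sc_co;
    double e_ch = (ch5 - ch4) / sc_ch;
    double err = std::sqrt(0.5 * (e_co * e_co + e_ch * e_ch));
    if (!std::isfinite(err))
      stop("integration error: non-finite state at t = %g (step %g)", t, h);
    if (err <= 1.0) {
      t += h;
      co = co5 < 0.0 ? 0.0 : co5;  // clip solver undershoot at zero
      ch = ch5 < 0.0 ? 0.0 : ch5;
      double fac = 0.9 * std::pow(std::max(err, 1e-12), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
    }
    if (h < 1e-14 * std::max(1.0, tspan))
      stop("integration error: step size underflow at t = %g", t);
    if (++n_steps > 50000000L)
      stop("integration error: step budget exceeded at t = %g", t);
  }
  h_next = h;
}

inline double clip_floor(double x) { return x < DENSITY_FLOOR ? 0.0 : x; }

// round-half-away-from-zero (mode 0), stochastic floor+Bernoulli (mode 1),
// passthrough (mode 2). Mode 1 consumes R's RNG stream.
inline double integerize1(double x, int mode) {
  if (x < 0.0) stop("integerize: negative count %g", x);
  switch (mode) {
  case 0: return std::floor(x + 0.5);
  case 1: {
    double fl = std::floor(x);
    double frac = x - fl;
    return fl + ((frac > 0.0 && unif_rand() < frac) ? 1.0 : 0.0);
  }
  default: return x;
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_derivs(NumericVector state, List params) {
  ModelP p = as_modelp(params);
  double dco, dch;
  derivs(state[0], state[1], p, dco, dch);
  return NumericVector::create(dco, dch);
}

// Dense trajectory on the grid seq(0, duration, by = dt_out) (final point
// appended if duration is not a multiple of dt_out). Columns: time, co, ch.
// [[Rcpp::export]]
NumericMatrix cpp_integrate(NumericVector state0, List params, double duration,
                            double dt_out, double rtol, double atol) {
  ModelP p = as_modelp(params);
  double co = state0[0], ch = state0[1];
  std::vector<double> ts;
  ts.push_back(0.0);
  long n_grid = (long)std::floor(duration / dt_out + 1e-9);
  for (long i = 1; i <= n_grid; i++) ts.push_back(i * dt_out);
  if (ts.back() < duration - 1e-9 * duration) ts.push_back(duration);
  NumericMatrix out(ts.size(), 3);
  out(0, 0) = 0.0; out(0, 1) = clip_floor(co); out(0, 2) = clip_floor(ch);
  double h_next = -1.0;
  for (size_t i = 1; i < ts.size(); i++) {
    advance(co, ch, p, ts[i] - ts[i - 1], rtol, atol, h_next);
    out(i, 0) = ts[i];
    out(i, 1) = clip_floor(co);
    out(i, 2) = clip_floor(ch);
  }
  colnames(out) = CharacterVector::create("time", "N_co", "N_ch");
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_integrate_end(NumericVector state0, List params,
                                double duration, double rtol, double atol) {
  ModelP p = as_modelp(params);
  double co = state0[0], ch = state0[1];
  double h_next = -1.0;
  advance(co, ch, p, duration, rtol, atol, h_next);
  return NumericVector::create(clip_floor(co), clip_floor(ch));
}

// Serial passage: grow for Tgrow, divide both densities by D, repeat.
// Returns per-cycle start/end states plus (optionally) the concatenated
// within-cycle trajectory sampled at dt_out.
// [[Rcpp::export]]
List cpp_serial_passage(NumericVector state0, List params, double D,
                        double Tgrow, int n_cycles, double dt_out,
                        double rtol, double atol, bool keep_traj) {
  ModelP p = as_modelp(params);
  double co = state0[0], ch = state0[1];
  long n_grid = (long)std::floor(Tgrow / dt_out + 1e-9);
  bool extra = (n_grid * dt_out < Tgrow - 1e-9 * Tgrow);
  long per_cycle = n_grid + (extra ? 1 : 0);  // points after t=0 per cycle
  NumericMatrix cycles(n_cycles, 6);
  std::vector<double> tr_t, tr_cyc, tr_co, tr_ch;
  if (keep_traj) {
    tr_t.reserve(1 + per_cycle * (size_t)n_cycles);
    tr_t.push_back(0.0); tr_cyc.push_back(1.0);
    tr_co.push_back(co); tr_ch.push_back(ch);
  }
  int completed = 0;
  bool extinct = false;
  double h_next = -1.0;
  for (int c = 0; c < n_cycles; c++) {
    cycles(c, 0) = c + 1;
    cycles(c, 1) = co; cycles(c, 2) = ch;
    double t_in = 0.0;
    for (long i = 1; i <= per_cycle; i++) {
      double t_next = (i <= n_grid) ? i * dt_out : Tgrow;
      advance(co, ch, p, t_next - t_in, rtol, atol, h_next);
      t_in = t_next;
      co = clip_floor(co); ch = clip_floor(ch);
      if (keep_traj) {
        tr_t.push_back(c * Tgrow + t_next);
        tr_cyc.push_back(c + 1);
        tr_co.push_back(co); tr_ch.push_back(ch);
      }
    }
    cycles(c, 3) = co; cycles(c, 4) = ch;
    double tot = co + ch;
    cycles(c, 5) = tot > 0.0 ? ch / tot : NA_REAL;
    completed = c + 1;
    if (tot <= 0.0) { extinct = true; break; }
    co /= D; ch /= D;  // exact dilution: no integerization in this engine
  }
  colnames(cycles) = CharacterVector::create(
    "cycle", "start_co", "start_ch", "end_co", "end_ch", "p_end");
  List out = List::create(
    _["cycles"] = cycles, _["completed"] = completed, _["extinct"] = extinct,
    _["final_co"] = co, _["final_ch"] = ch);
  if (keep_traj) {
    size_t n = tr_t.size();
    NumericMatrix traj(n, 4);
    for (size_t i = 0; i < n; i++) {
      traj(i, 0) = tr_t[i]; traj(i, 1) = tr_cyc[i];
      traj(i, 2) = tr_co[i]; traj(i, 3) = tr_ch[i];
    }
    colnames(traj) = CharacterVector::create("time", "cycle", "N_co", "N_ch");
    out["trajectory"] = traj;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_grow_all(NumericMatrix subpops, List params, double Tgrow,
                           double rtol, double atol) {
  ModelP p = as_modelp(params);
  int M = subpops.nrow();
  NumericMatrix out(M, 2);
  for (int i = 0; i < M; i++) {
    double co = subpops(i, 0), ch = subpops(i, 1);
    double h_next = -1.0;
    try {
      advance(co, ch, p, Tgrow, rtol, atol, h_next);
    } catch (std::exception& e) {
      stop("growth failed in subpopulation %d: %s", i + 1, e.what());
    }
    out(i, 0) = clip_floor(co);
    out(i, 1) = clip_floor(ch);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_integerize(NumericVector x, int mode) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = integerize1(x[i], mode);
  return out;
}

// round(F*M) pairwise mixing events. Each event draws two distinct
// subpopulations uniformly, pools their (integerized) counts per strain and
// replaces both with the integerized pooled average. RNG draw order: for each
// event, index i then rejection draws for j != i, then any stochastic
// rounding draws (co before ch).
// [[Rcpp::export]]
NumericMatrix cpp_mix_pairs(NumericMatrix subpops, double F, int mode) {
  int M = subpops.nrow();
  if (M < 2) stop("mixing requires at least two subpopulations");
  NumericMatrix out = clone(subpops);
  long n_events = (long)std::floor(F * M + 0.5);
  for (long e = 0; e < n_events; e++) {
    int i = (int)std::floor(unif_rand() * M);
    if (i >= M) i = M - 1;
    int j = i;
    while (j == i) {
      j = (int)std::floor(unif_rand() * M);
      if (j >= M) j = M - 1;
    }
    double co_tot = integerize1(out(i, 0), mode) + integerize1(out(j, 0), mode);
    double ch_tot = integerize1(out(i, 1), mode) + integerize1(out(j, 1), mode);
    double co_new = integerize1(co_tot / 2.0, mode);
    double ch_new = integerize1(ch_tot / 2.0, mode);
    out(i, 0) = co_new; out(j, 0) = co_new;
    out(i, 1) = ch_new; out(j, 1) = ch_new;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bottleneck_all(NumericMatrix subpops, double D, int mode) {
  int M = subpops.nrow();
  NumericMatrix out(M, 2);
  for (int i = 0; i < M; i++) {
    out(i, 0) = integerize1(subpops(i, 0) / D, mode);
    out(i, 1) = integerize1(subpops(i, 1) / D, mode);
  }
  return out;
}

// Full scenario-3 life cycle per growth cycle:
//   grow_all -> integerize -> mix_pairs -> bottleneck_all.
// Per cycle records the post-bottleneck global cheat proportion, the mean and
// CV (sd/mean, n-1 denominator) of per-subpopulation cheat relative fitness
// (realized Malthusian ratio over the growth phase), and the count of
// subpopulations where that fitness is defined.
// [[Rcpp::export]]
List cpp_run_metapopulation(List params, int M, double n0_co, double n0_ch,
                            double F, double D, double Tgrow, int n_cycles,
                            int mode, double rtol, double atol,
                            bool keep_fitness) {
  ModelP p = as_modelp(params);
  NumericMatrix sub(M, 2);
  for (int i = 0; i < M; i++) { sub(i, 0) = n0_co; sub(i, 1) = n0_ch; }
  NumericMatrix cycles(n_cycles, 5);
  NumericMatrix fitmat;
  if (keep_fitness) fitmat = NumericMatrix(M, n_cycles);
  int completed = 0;
  bool extinct = false;
  for (int c = 0; c < n_cycles; c++) {
    NumericMatrix start = clone(sub);
    NumericMatrix grown = cpp_grow_all(sub, params, Tgrow, rtol, atol);
    // relative fitness: ln fold-change of cheats over ln fold-change of
    // cooperators during the growth phase, on pre-integerization densities
    std::vector<double> ws;
    ws.reserve(M);
    for (int i = 0; i < M; i++) {
      double w = NA_REAL;
      if (start(i, 0) > 0.0 && start(i, 1) > 0.0 &&
          grown(i, 0) > 0.0 && grown(i, 1) > 0.0) {
        double gco = std::log(grown(i, 0) / start(i, 0));
        double gch = std::log(grown(i, 1) / start(i, 1));
        if (std::fabs(gco) > 1e-12) {
          w = gch / gco;
          ws.push_back(w);
        }
      }
      if (keep_fitness) fitmat(i, c) = w;
    }
    int n_w = (int)ws.size();
    for (int i = 0; i < M; i++) {
      grown(i, 0) = integerize1(grown(i, 0), mode);
      grown(i, 1) = integerize1(grown(i, 1), mode);
    }
    NumericMatrix mixed = cpp_mix_pairs(grown, F, mode);
    sub = cpp_bottleneck_all(mixed, D, mode);
    double tot_co = 0.0, tot_ch = 0.0;
    for (int i = 0; i < M; i++) { tot_co += sub(i, 0); tot_ch += sub(i, 1); }
    double tot = tot_co + tot_ch;
    cycles(c, 0) = c + 1;
    cycles(c, 1) = tot > 0.0 ? tot_ch / tot : NA_REAL;
    if (n_w >= 1) {
      double mean_w = 0.0;
      for (double w : ws) mean_w += w;
      mean_w /= n_w;
      cycles(c, 2) = mean_w;
      if (n_w >= 2) {
        double ss = 0.0;  // two-pass: stable when all values coincide
        for (double w : ws) ss += (w - mean_w) * (w - mean_w);
        double sd_w = std::sqrt(ss / (n_w - 1));
        cycles(c, 3) = mean_w != 0.0 ? sd_w / mean_w : NA_REAL;
      } else {
        cycles(c, 3) = NA_REAL;
      }
    } else {
      cycles(c, 2) = NA_REAL; cycles(c, 3) = NA_REAL;
    }
    cycles(c, 4) = n_w;
    completed = c + 1;
    if (tot <= 0.0) { extinct = true; break; }
  }
  colnames(cycles) = CharacterVector::create(
    "cycle", "p_global", "mean_fitness", "cv_fitness", "n_fitness");
  List out = List::create(
    _["cycles"] = cycles, _["completed"] = completed, _["extinct"] = extinct,
    _["subpops"] = sub);
  if (keep_fitness) out["fitness"] = fitmat;
  return out;
}
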