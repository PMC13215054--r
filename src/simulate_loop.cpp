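#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-extent equilibration: x is the adenylate-kinase extent
// (AMP + ATP -> 2 ADP), y the arginine-kinase extent (ADP + ArgP -> ATP + Arg).
// Damped Newton with nested-bisection fallback; conservation of the
// adenine pool, guanidino pool and phosphoryl tally is exact by construction.

struct State {
  double atp, adp, amp, arg, argp, pi;
};

static inline State apply_extents(const State &s0, double x, double y) {
  State s;
  s.atp = s0.atp - x + y;
  s.adp = s0.adp + 2.0 * x - y;
  s.amp = s0.amp - x;
  s.arg = s0.arg + y;
  s.argp = s0.argp - y;
  s.pi = s0.pi;
  return s;
}

static inline void residuals(const State &s, double k_ad, double k_ph,
                             double *f1, double *f2) {
  *f1 = k_ad * s.atp * s.amp - s.adp * s.adp;
  *f2 = k_ph * s.adp * s.argp - s.atp * s.arg;
}

static inline bool feasible(const State &s) {
  return s.atp >= 0 && s.adp >= 0 && s.amp >= 0 && s.arg >= 0 && s.argp >= 0;
}

static double solve_ak_extent(const State &s0, double k_ad, double y) {
  double xlo = (y - s0.adp) / 2.0;
  double xhi = std::min(s0.amp, s0.atp + y);
  if (xhi <= xlo) return xlo;
  for (int i = 0; i < 200; ++i) {
    double xm = 0.5 * (xlo + xhi);
    State s = apply_extents(s0, xm, y);
    double g = k_ad * s.atp * s.amp - s.adp * s.adp;
    if (g > 0) xlo = xm; else xhi = xm;
    if (xhi - xlo < 1e-15 * std::max(1.0, std::fabs(xm))) break;
  }
  return 0.5 * (xlo + xhi);
}

// ArgK residual at (x(y), y) with x(y) solving the AK relation for given y.
static double nested_g(const State &s0, double k_ad, double k_ph, double y,
                       double *x_out) {
  double x = solve_ak_extent(s0, k_ad, y);
  State s = apply_extents(s0, x, y);
  if (x_out) *x_out = x;
  return k_ph * s.adp * s.argp - s.atp * s.arg;
}

// Nested bisection over the y-range where the inner AK problem is feasible.
// A strict interior sign change excludes the vacuous boundary roots
// (e.g. ATP = ADP = 0) that satisfy both relations trivially.
static void solve_nested_extents(const State &s0, double k_ad, double k_ph,
                                 double *x_out, double *y_out) {
  const int grid_n = 64;
  double ylo = std::max(-s0.arg, -(2.0 * s0.atp + s0.adp));
  double yhi = std::min(s0.argp, 2.0 * s0.amp + s0.adp);
  if (yhi <= ylo) {
    *y_out = ylo;
    *x_out = solve_ak_extent(s0, k_ad, ylo);
    return;
  }
  double ys[grid_n], gs[grid_n];
  for (int i = 0; i < grid_n; ++i) {
    ys[i] = ylo + (yhi - ylo) * i / (grid_n - 1.0);
    gs[i] = nested_g(s0, k_ad, k_ph, ys[i], NULL);
  }
  int idx = -1;
  for (int i = 0; i + 1 < grid_n; ++i)
    if (gs[i] > 0 && gs[i + 1] <= 0) { idx = i; break; }
  if (idx < 0)
    for (int i = 0; i + 1 < grid_n; ++i)
      if (gs[i] >= 0 && gs[i + 1] <= 0) { idx = i; break; }
  if (idx < 0) {
    double y = (gs[0] <= 0) ? ylo : yhi;
    *y_out = y;
    *x_out = solve_ak_extent(s0, k_ad, y);
    return;
  }
  double lo = ys[idx], hi = ys[idx + 1];
  for (int it = 0; it < 200; ++it) {
    double m = 0.5 * (lo + hi);
    if (nested_g(s0, k_ad, k_ph, m, NULL) > 0) lo = m; else hi = m;
    if (hi - lo < 1e-15 * std::max(1.0, std::fabs(m))) break;
  }
  *y_out = 0.5 * (lo + hi);
  *x_out = solve_ak_extent(s0, k_ad, *y_out);
}

static bool rel_ok(const State &s, double k_ad, double k_ph,
                   bool phosphagen, double tol) {
  double f1, f2;
  residuals(s, k_ad, k_ph, &f1, &f2);
  double sc1 = std::max(k_ad * s.atp * s.amp, s.adp * s.adp);
  double sc2 = std::max(k_ph * s.adp * s.argp, s.atp * s.arg);
  bool ok1 = (sc1 <= 0) ? true : std::fabs(f1) / sc1 <= tol;
  bool ok2 = !phosphagen || ((sc2 <= 0) ? true : std::fabs(f2) / sc2 <= tol);
  return ok1 && ok2;
}

// returns false on non-convergence
static bool equilibrate_state(State &s0, double k_ad, double k_ph,
                              bool phosphagen, double tol, int max_iter) {
  if (!phosphagen) {
    double x = solve_ak_extent(s0, k_ad, 0.0);
    State s = apply_extents(s0, x, 0.0);
    s.arg = s0.arg; s.argp = s0.argp;
    if (s.atp < 0) s.atp = 0; if (s.adp < 0) s.adp = 0; if (s.amp < 0) s.amp = 0;
    s0 = s;
    return true;
  }
  // An interior input has an interior equilibrium; a converged state sitting
  // on the ATP = 0 or ADP = 0 boundary is a vacuous root and is rejected.
  const bool interior_in = s0.atp > 0 && s0.adp > 0;
  const double tiny = 1e-13 * (s0.atp + s0.adp + s0.amp);

  double x = 0.0, y = 0.0;
  State s = s0;
  for (int it = 0; it < max_iter; ++it) {
    if (rel_ok(s, k_ad, k_ph, true, tol)) {
      if (interior_in && (s.atp <= tiny || s.adp <= tiny)) {
        solve_nested_extents(s0, k_ad, k_ph, &x, &y);
        s = apply_extents(s0, x, y);
        continue;
      }
      if (s.atp < 0) s.atp = 0; if (s.adp < 0) s.adp = 0;
      if (s.amp < 0) s.amp = 0; if (s.arg < 0) s.arg = 0;
      if (s.argp < 0) s.argp = 0;
      s0 = s;
      return true;
    }
    double f1, f2;
    residuals(s, k_ad, k_ph, &f1, &f2);
    double j11 = -k_ad * (s.amp + s.atp) - 4.0 * s.adp;
    double j12 = k_ad * s.amp + 2.0 * s.adp;
    double j21 = 2.0 * k_ph * s.argp + s.arg;
    double j22 = -k_ph * (s.argp + s.adp) - (s.arg + s.atp);
    double det = j11 * j22 - j12 * j21;
    bool accepted = false;
    if (std::isfinite(det) && std::fabs(det) > 1e-300) {
      double dx = (-f1 * j22 + f2 * j12) / det;
      double dy = (-f2 * j11 + f1 * j21) / det;
      double lambda = 1.0;
      for (int d = 0; d < 30; ++d) {
        double xn = x + lambda * dx, yn = y + lambda * dy;
        State sn = apply_extents(s0, xn, yn);
        double g1, g2;
        residuals(sn, k_ad, k_ph, &g1, &g2);
        if (feasible(sn) &&
            std::fabs(g1) + std::fabs(g2) < std::fabs(f1) + std::fabs(f2)) {
          x = xn; y = yn; s = sn; accepted = true;
          break;
        }
        lambda *= 0.5;
      }
    }
    if (!accepted) {
      solve_nested_extents(s0, k_ad, k_ph, &x, &y);
      s = apply_extents(s0, x, y);
    }
  }
  if (rel_ok(s, k_ad, k_ph, true, tol) &&
      !(interior_in && (s.atp <= tiny || s.adp <= tiny))) {
    if (s.atp < 0) s.atp = 0; if (s.adp < 0) s.adp = 0;
    if (s.amp < 0) s.amp = 0; if (s.arg < 0) s.arg = 0;
    if (s.argp < 0) s.argp = 0;
    s0 = s;
    return true;
  }
  return false;
}

// [[Rcpp::export(name = ".simulate_loop_cpp")]]
List simulate_loop_cpp(NumericVector state0,       // atp, adp, amp, arg, argp, pi
                       double dt, int n_steps, int record_stride,
                       IntegerVector spike_step,   // 1-based step index per spike
                       NumericVector comp_height,  // cost_mM / tau per component
                       NumericVector comp_tau,
                       double base_rate,
                       bool has_production,
                       double prod_base_rate, double turnover_base,
                       double hill_k, double hill_h,
                       double max_rate, double cap_exponent,
                       bool do_equilibrate, bool phosphagen,
                       double k_ad, double k_ph,
                       double eq_tol, int eq_max_iter) {
  const int nc = comp_height.size();
  std::vector<double> acc(nc, 0.0), decay(nc);
  for (int j = 0; j < nc; ++j) decay[j] = std::exp(-dt / comp_tau[j]);

  State s;
  s.atp = state0[0]; s.adp = state0[1]; s.amp = state0[2];
  s.arg = state0[3]; s.argp = state0[4]; s.pi = state0[5];

  int n_rec = n_steps / record_stride + 1;
  NumericVector r_time(n_rec), r_atp(n_rec), r_adp(n_rec), r_amp(n_rec),
      r_arg(n_rec), r_argp(n_rec), r_pi(n_rec), r_cons(n_rec), r_prod(n_rec);

  int sp = 0, n_sp = spike_step.size(), rec = 0;
  std::string err;
  double err_time = NA_REAL;

  for (int i = 0; i <= n_steps; ++i) {
    // deposit spikes assigned to this grid point
    while (sp < n_sp && spike_step[sp] == i + 1) {
      for (int j = 0; j < nc; ++j) acc[j] += comp_height[j];
      ++sp;
    }
    double cons = base_rate;
    for (int j = 0; j < nc; ++j) cons += acc[j];

    double prod = 0.0;
    if (has_production) {
      double es = s.atp / (s.adp * s.pi);
      double pcc = 1.0 / (1.0 + std::pow(es / hill_k, hill_h));
      prod = prod_base_rate * pcc / turnover_base;
      if (prod > 0)
        prod = std::pow(std::pow(prod, -cap_exponent) +
                        std::pow(max_rate, -cap_exponent), -1.0 / cap_exponent);
    }

    if (i % record_stride == 0 && rec < n_rec) {
      r_time[rec] = i * dt;
      r_atp[rec] = s.atp; r_adp[rec] = s.adp; r_amp[rec] = s.amp;
      r_arg[rec] = s.arg; r_argp[rec] = s.argp; r_pi[rec] = s.pi;
      r_cons[rec] = cons; r_prod[rec] = prod;
      ++rec;
    }
    if (i == n_steps) break;

    // advance one step: consume/produce then equilibrate, with local
    // subdivision if the update would drive a concentration negative
    bool ok = false;
    for (int m = 0; m <= 10 && !ok; ++m) {
      int n_sub = 1 << m;
      double h = dt / n_sub;
      State trial = s;
      ok = true;
      for (int u = 0; u < n_sub; ++u) {
        double p_sub = 0.0;
        if (has_production) {
          double es = trial.atp / (trial.adp * trial.pi);
          double pcc = 1.0 / (1.0 + std::pow(es / hill_k, hill_h));
          p_sub = prod_base_rate * pcc / turnover_base;
          if (p_sub > 0)
            p_sub = std::pow(std::pow(p_sub, -cap_exponent) +
                             std::pow(max_rate, -cap_exponent),
                             -1.0 / cap_exponent);
        }
        double flux = (p_sub - cons) * h;
        trial.atp += flux; trial.adp -= flux; trial.pi -= flux;
        if (trial.atp < 0 || trial.adp < 0 || trial.pi < 0) { ok = false; break; }
        if (do_equilibrate) {
          if (!equilibrate_state(trial, k_ad, k_ph, phosphagen,
                                 eq_tol, eq_max_iter)) {
            err = "equilibration failed to converge";
            err_time = i * dt;
            ok = false;
            m = 11;  // no point subdividing further
            break;
          }
        }
      }
      if (ok) s = trial;
    }
    if (!ok) {
      if (err.empty()) err = "step would drive a concentration negative";
      err_time = i * dt;
      break;
    }
    for (int j = 0; j < nc; ++j) acc[j] *= decay[j];
  }

  return List::create(_["time"] = r_time, _["atp"] = r_atp, _["adp"] = r_adp,
                      _["amp"] = r_amp, _["arg"] = r_arg, _["argp"] = r_argp,
                      _["pi"] = r_pi, _["consumption"] = r_cons,
                      _["production"] = r_prod, _["n_recorded"] = rec,
                      _["error"] = err, _["error_time"] = err_time);
}
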