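#include <Rcpp.h>
using namespace Rcpp;

// Discrete-day exponential excitation kernel.
//
// An event on day d contributes P(t | d, T) = exp(-(t-d-1)/T) - exp(-(t-d)/T)
// to the expected count on day t > d.  Writing P = (e^{1/T} - 1) e^{-(t-d)/T}
// gives the O(n) recursion A(t+1) = e^{-1/T} (A(t) + c(t)) for the
// exponentially discounted event history A(t) = sum_{d<t} c(d) e^{-(t-d)/T}.

// [[Rcpp::export]]
NumericVector cpp_excite_sum(NumericVector counts, double T_excite) {
  int n = counts.size();
  NumericVector g(n);
  double decay = std::exp(-1.0 / T_excite);
  double scale = std::exp(1.0 / T_excite) - 1.0;
  double A = 0.0;
  for (int t = 0; t < n; ++t) {
    g[t] = scale * A;
    A = decay * (A + counts[t]);
  }
  return g;
}

static double poisson_core(const NumericVector& counts, const NumericVector& mu) {
  // sum c log mu - mu, without the lgamma(c+1) data constant
  int n = counts.size();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (counts[t] > 0) {
      if (mu[t] <= 0.0) return R_NegInf;
      ll += counts[t] * std::log(mu[t]);
    }
    ll -= mu[t];
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_poisson_loglik(NumericVector counts, NumericVector mu) {
  double ll = poisson_core(counts, mu);
  if (ll == R_NegInf) return ll;
  for (int t = 0; t < counts.size(); ++t)
    ll -= R::lgammafn(counts[t] + 1.0);
  return ll;
}

static double obj_bs(const NumericVector& counts, const NumericVector& base,
                     const NumericVector& g, double b, double s) {
  int n = counts.size();
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double mu = b * base[t] + s * g[t];
    if (counts[t] > 0) {
      if (mu <= 0.0) return R_NegInf;
      ll += counts[t] * std::log(mu);
    }
    ll -= mu;
  }
  return ll;
}

// Maximise the per-day Poisson log-likelihood over (b, s) with mean
// mu_t = b * base_t + s * g_t, subject to b >= b_min, 0 <= s <= s_max.
// The objective is concave on the feasible region, so a projected Newton
// step with backtracking (projected-gradient fallback) converges reliably.
// [[Rcpp::export]]
NumericVector cpp_fit_bs(NumericVector counts, NumericVector base,
                         NumericVector g, double s_max,
                         double b_init, double s_init) {
  int n = counts.size();
  const double b_min = 1e-12;
  double ctot = 0.0, gtot = 0.0;
  for (int t = 0; t < n; ++t) { ctot += counts[t]; gtot += g[t]; }

  if (ctot == 0.0) {
    // all-zero series: likelihood decreasing in both parameters
    NumericVector out = NumericVector::create(b_min, 0.0,
      obj_bs(counts, base, g, b_min, 0.0), 1.0);
    return out;
  }

  double b = (b_init > b_min) ? b_init : b_min;
  double s = std::min(std::max(s_init, 0.0), s_max);
  if (gtot <= 0.0) s = 0.0;  // no excitable history: s unidentified, pin at 0
  double f = obj_bs(counts, base, g, b, s);
  if (f == R_NegInf) { b = ctot / n; s = 0.0; f = obj_bs(counts, base, g, b, s); }

  bool converged = false;
  for (int iter = 0; iter < 200; ++iter) {
    // gradient and Hessian of the concave objective
    double gb = 0.0, gs = 0.0, hbb = 0.0, hbs = 0.0, hss = 0.0;
    for (int t = 0; t < n; ++t) {
      double mu = b * base[t] + s * g[t];
      double r = (mu > 0.0) ? (counts[t] / mu - 1.0) : 0.0;
      gb += r * base[t];
      gs += r * g[t];
      if (mu > 0.0 && counts[t] > 0) {
        double w = counts[t] / (mu * mu);
        hbb -= w * base[t] * base[t];
        hbs -= w * base[t] * g[t];
        hss -= w * g[t] * g[t];
      }
    }

    // KKT check with active bounds
    double kb = (b <= b_min && gb < 0.0) ? 0.0 : gb;
    double ks = gs;
    if ((s <= 0.0 && gs < 0.0) || (s >= s_max && gs > 0.0)) ks = 0.0;
    if (std::fabs(kb) < 1e-8 * (1.0 + ctot) && std::fabs(ks) < 1e-8 * (1.0 + ctot)) {
      converged = true;
      break;
    }

    // active-set Newton: when s sits on a bound with the gradient pointing
    // outward, drop to a 1-D Newton step in b (keeps the line search from
    // grinding against the boundary)
    bool s_active = (s <= 0.0 && gs <= 0.0) || (s >= s_max && gs >= 0.0);
    double det = hbb * hss - hbs * hbs;
    double db, ds;
    if (s_active) {
      ds = 0.0;
      db = (hbb < 0.0) ? -gb / hbb : gb;
    } else if (std::fabs(det) > 1e-300 && hbb < 0.0) {
      db = -( hss * gb - hbs * gs) / det;
      ds = -(-hbs * gb + hbb * gs) / det;
    } else {
      db = gb; ds = gs;
    }

    // Newton decrement: expected gain ~ decr/2; once it is negligible on
    // the likelihood scale the optimum is reached (concave objective)
    double decr = gb * db + gs * ds;
    if (decr >= 0.0 && decr < 1e-9) { converged = true; break; }

    double alpha = 1.0;
    bool improved = false;
    for (int ls = 0; ls < 40; ++ls) {
      double bn = std::max(b + alpha * db, b_min);
      double sn = std::min(std::max(s + alpha * ds, 0.0), s_max);
      double fn = obj_bs(counts, base, g, bn, sn);
      if (fn > f) {
        b = bn; s = sn; f = fn; improved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!improved) {
      // ascent direction yields no representable improvement: at optimum
      converged = true;
      break;
    }
  }

  return NumericVector::create(b, s, f, converged ? 1.0 : 0.0);
}

// Maximise over the baseline scale b alone, with a fixed additive offset
// (the excitation term with N_secondary held at a profile value):
// mu_t = b * base_t + offset_t.  1-D concave Newton with bisection safeguard.
// [[Rcpp::export]]
NumericVector cpp_fit_b(NumericVector counts, NumericVector base,
                        NumericVector offset, double b_init) {
  int n = counts.size();
  const double b_min = 1e-12;
  double b = (b_init > b_min) ? b_init : b_min;
  double lo = b_min, hi = R_PosInf;
  for (int iter = 0; iter < 100; ++iter) {
    double gb = 0.0, hbb = 0.0;
    for (int t = 0; t < n; ++t) {
      double mu = b * base[t] + offset[t];
      if (mu <= 0.0) continue;
      gb += (counts[t] / mu - 1.0) * base[t];
      if (counts[t] > 0)
        hbb -= counts[t] * base[t] * base[t] / (mu * mu);
    }
    if (std::fabs(gb) < 1e-10 * (1.0 + b)) break;
    if (gb > 0.0) lo = b; else hi = b;
    double bn = (hbb < 0.0) ? b - gb / hbb : b * (gb > 0.0 ? 2.0 : 0.5);
    if (bn <= lo || bn >= hi || !std::isfinite(bn))
      bn = std::isfinite(hi) ? 0.5 * (lo + hi) : 2.0 * std::max(b, 1e-8);
    if (std::fabs(bn - b) < 1e-14 * (1.0 + b)) { b = std::max(bn, b_min); break; }
    b = std::max(bn, b_min);
  }
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double mu = b * base[t] + offset[t];
    if (counts[t] > 0) {
      if (mu <= 0.0) { ll = R_NegInf; break; }
      ll += counts[t] * std::log(mu);
    }
    ll -= mu;
  }
  return NumericVector::create(b, ll);
}

// Profile over T_excite with N_secondary fixed at s0: for each T maximise
// over the baseline scale only.  Returns rows of (T, b_hat, loglik).
// [[Rcpp::export]]
NumericMatrix cpp_profile_T_fixed_s(NumericVector counts, NumericVector base,
                                    NumericVector T_grid, double s0,
                                    double b_init) {
  int m = T_grid.size(), n = counts.size();
  NumericMatrix out(m, 3);
  NumericVector offset(n);
  double b_ws = b_init;
  for (int i = 0; i < m; ++i) {
    NumericVector g = cpp_excite_sum(counts, T_grid[i]);
    for (int t = 0; t < n; ++t) offset[t] = s0 * g[t];
    NumericVector fit = cpp_fit_b(counts, base, offset, b_ws);
    b_ws = fit[0];
    out(i, 0) = T_grid[i];
    out(i, 1) = fit[0];
    out(i, 2) = fit[1];
  }
  return out;
}

// Profile the likelihood over a grid of T_excite values, maximising (b, s)
// at each.  Returns one row per grid point: T, b_hat, s_hat, loglik
// (lgamma data constant excluded), convergence flag.
// [[Rcpp::export]]
NumericMatrix cpp_profile_T(NumericVector counts, NumericVector base,
                            NumericVector T_grid, double s_max,
                            double b_init, double s_init) {
  int m = T_grid.size();
  NumericMatrix out(m, 5);
  double b_ws = b_init, s_ws = s_init;  // warm start along the grid
  for (int i = 0; i < m; ++i) {
    NumericVector g = cpp_excite_sum(counts, T_grid[i]);
    NumericVector fit = cpp_fit_bs(counts, base, g, s_max, b_ws, s_ws);
    b_ws = fit[0];
    s_ws = (fit[1] > 1e-6) ? fit[1] : s_init;
    out(i, 0) = T_grid[i];
    out(i, 1) = fit[0];
    out(i, 2) = fit[1];
    out(i, 3) = fit[2];
    out(i, 4) = fit[3];
  }
  return out;
}

struct ProfileEval {
  // warm-started profile evaluation state shared along a T search
  double b_ws, s_ws;
  double eval(const NumericVector& counts, const NumericVector& base,
              double Tv, double s_max, double* b_out = 0, double* s_out = 0,
              double* conv = 0) {
    NumericVector g = cpp_excite_sum(counts, Tv);
    NumericVector fit = cpp_fit_bs(counts, base, g, s_max, b_ws, s_ws);
    b_ws = fit[0];
    if (fit[1] > 1e-6) s_ws = fit[1];
    if (b_out) *b_out = fit[0];
    if (s_out) *s_out = fit[1];
    if (conv) *conv = fit[3];
    return fit[2];
  }
};

// Golden-section maximisation of the T_excite profile likelihood on
// log(T) in [T_lo, T_hi].  Returns (T, b, s, core, converged).
// [[Rcpp::export]]
NumericVector cpp_refine_T(NumericVector counts, NumericVector base,
                           double T_lo, double T_hi, double s_max,
                           double b_init, double s_init, double tol_log) {
  const double gr = 0.3819660112501051;  // 2 - golden ratio
  ProfileEval pe; pe.b_ws = b_init; pe.s_ws = s_init;
  double a = std::log(T_lo), b = std::log(T_hi);
  double x1 = a + gr * (b - a), x2 = b - gr * (b - a);
  double f1 = pe.eval(counts, base, std::exp(x1), s_max);
  double f2 = pe.eval(counts, base, std::exp(x2), s_max);
  int guard = 0;
  while (b - a > tol_log && ++guard < 100) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = b - gr * (b - a);
      f2 = pe.eval(counts, base, std::exp(x2), s_max);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = a + gr * (b - a);
      f1 = pe.eval(counts, base, std::exp(x1), s_max);
    }
  }
  double Tbest = std::exp(0.5 * (a + b));
  double bb, ss, cv;
  double core = pe.eval(counts, base, Tbest, s_max, &bb, &ss, &cv);
  return NumericVector::create(Tbest, bb, ss, core, cv);
}

// One full-model fit: warm-started profile over the T grid, then
// golden-section refine between the best point's neighbours (only when the
// branching ratio is off its zero boundary).  Returns
// (T, b, s, core, converged).
static NumericVector fit_full_one(const NumericVector& counts,
                                  const NumericVector& base,
                                  const NumericVector& T_grid,
                                  double s_max, double b_init,
                                  double s_init, double tol_log,
                                  bool refine) {
  int m = T_grid.size();
  ProfileEval pe; pe.b_ws = b_init; pe.s_ws = s_init;
  double bestc = R_NegInf, bestT = T_grid[0], bestb = b_init, bests = 0.0;
  double conv_all = 1.0;
  int besti = 0;
  for (int i = 0; i < m; ++i) {
    double bb, ss, cv;
    double core = pe.eval(counts, base, T_grid[i], s_max, &bb, &ss, &cv);
    if (cv == 0.0) conv_all = 0.0;
    if (core > bestc) {
      bestc = core; bestT = T_grid[i]; bestb = bb; bests = ss; besti = i;
    }
  }
  if (refine && bests > 1e-8) {
    double lo = T_grid[besti > 0 ? besti - 1 : 0];
    double hi = T_grid[besti < m - 1 ? besti + 1 : m - 1];
    if (hi > lo) {
      NumericVector r = cpp_refine_T(counts, base, lo, hi, s_max,
                                     bestb, bests, tol_log);
      if (r[3] > bestc) {
        bestT = r[0]; bestb = r[1]; bests = r[2]; bestc = r[3];
        if (r[4] == 0.0) conv_all = 0.0;
      }
    }
  }
  return NumericVector::create(bestT, bestb, bests, bestc, conv_all);
}

// [[Rcpp::export]]
NumericVector cpp_fit_full(NumericVector counts, NumericVector base,
                           NumericVector T_grid, double s_max,
                           double b_init, double s_init, double tol_log,
                           bool refine) {
  return fit_full_one(counts, base, T_grid, s_max, b_init, s_init,
                      tol_log, refine);
}

// Parametric-bootstrap engine for the contagion LRT with a scale-form
// baseline: each replicate draws y ~ Poisson(null_mu), fits the null by
// its closed-form scale MLE and the full model by the same grid-plus-
// refine profile used for the observed fit, and records
// Lambda* = 2 (core_full - core_null).  Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_lrt_boot(NumericVector null_mu, NumericVector base,
                           NumericVector T_grid, double s_max, int n_boot,
                           double tol_log, bool refine) {
  int n = null_mu.size();
  NumericVector lambdas(n_boot), y(n);
  double base_tot = 0.0;
  for (int t = 0; t < n; ++t) base_tot += base[t];
  RNGScope rngScope;
  for (int rep = 0; rep < n_boot; ++rep) {
    double ctot = 0.0;
    for (int t = 0; t < n; ++t) { y[t] = R::rpois(null_mu[t]); ctot += y[t]; }
    double core_null;
    if (ctot == 0.0) { lambdas[rep] = 0.0; continue; }
    double b0 = ctot / base_tot;
    core_null = 0.0;
    for (int t = 0; t < n; ++t) {
      double mu = b0 * base[t];
      if (y[t] > 0) core_null += y[t] * std::log(mu);
      core_null -= mu;
    }
    NumericVector full = fit_full_one(y, base, T_grid, s_max, b0, 0.1,
                                      tol_log, refine);
    double lam = 2.0 * (full[3] - core_null);
    lambdas[rep] = lam > 0.0 ? lam : 0.0;
  }
  return lambdas;
}

// Sequential simulation of the daily self-excitation process: counts(t) ~
// Poisson(mu_t), mu_t = base_mu_t + Nsec * (e^{1/T}-1) * A(t), with A built
// from already-generated history (only days <= t-1 excite day t).  Uses R's
// RNG so set.seed() on the R side gives reproducibility.
// [[Rcpp::export]]
NumericVector cpp_sim_hawkes(NumericVector base_mu, double N_secondary,
                             double T_excite) {
  int n = base_mu.size();
  NumericVector counts(n);
  double decay = std::exp(-1.0 / T_excite);
  double scale = std::exp(1.0 / T_excite) - 1.0;
  double A = 0.0;
  RNGScope rngScope;
  for (int t = 0; t < n; ++t) {
    double mu = base_mu[t] + N_secondary * scale * A;
    if (mu < 0.0) mu = 0.0;
    counts[t] = R::rpois(mu);
    A = decay * (A + counts[t]);
  }
  return counts;
}
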