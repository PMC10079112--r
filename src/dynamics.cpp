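#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time active-fraction dynamics on a signed, directed network.
//
// W is the n x n weight matrix with W(s, t) the signed weight of the edge
// s -> t; a stored 0 means "no edge".  For target i the positive incoming
// weights are the upregulatory coefficients k_{i,j}, the magnitudes of the
// negative ones the downregulatory coefficients I_{i,j}.  Each node pays a
// flat per-step use cost proportional to its out-degree (self-edges count).

static inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

static void out_degrees(const NumericMatrix& W, std::vector<int>& deg) {
  int n = W.nrow();
  deg.assign(n, 0);
  for (int s = 0; s < n; ++s) {
    int d = 0;
    for (int t = 0; t < n; ++t) if (W(s, t) != 0.0) ++d;
    deg[s] = d;
  }
}

static void step_inplace(const NumericMatrix& W, const std::vector<int>& deg,
                         double use_coef, const std::vector<double>& p,
                         std::vector<double>& out) {
  int n = W.nrow();
  for (int i = 0; i < n; ++i) {
    double up = 0.0, down = 0.0;
    for (int j = 0; j < n; ++j) {
      double w = W(j, i);
      if (w > 0.0)      up   += w * p[j];
      else if (w < 0.0) down += (-w) * p[j];
    }
    double delta = (1.0 - p[i]) * up - p[i] * down - use_coef * deg[i];
    out[i] = clamp01(p[i] + delta);
  }
}

// [[Rcpp::export(name = ".cpp_step")]]
NumericVector cpp_step(NumericMatrix W, NumericVector p, double use_coef) {
  int n = W.nrow();
  if (W.ncol() != n || p.size() != n)
    stop("weight matrix and state dimensions disagree");
  std::vector<int> deg;
  out_degrees(W, deg);
  std::vector<double> cur(p.begin(), p.end()), nxt(n);
  step_inplace(W, deg, use_coef, cur, nxt);
  return NumericVector(nxt.begin(), nxt.end());
}

// Iterate from a uniform (or supplied) state until the effector level moves
// by less than tol between consecutive steps, or max_steps is hit.
// [[Rcpp::export(name = ".cpp_equilibrium")]]
List cpp_equilibrium(NumericMatrix W, NumericVector p0, double use_coef,
                     int eff_idx, double tol, int max_steps) {
  int n = W.nrow();
  if (W.ncol() != n || p0.size() != n) stop("dimension mismatch");
  if (eff_idx < 1 || eff_idx > n) stop("effector index out of range");
  std::vector<int> deg;
  out_degrees(W, deg);
  std::vector<double> cur(p0.begin(), p0.end()), nxt(n);
  int e = eff_idx - 1;
  bool converged = false;
  int steps = 0;
  for (int t = 0; t < max_steps; ++t) {
    step_inplace(W, deg, use_coef, cur, nxt);
    ++steps;
    double change = std::fabs(nxt[e] - cur[e]);
    cur.swap(nxt);
    if (change < tol) { converged = true; break; }
  }
  return List::create(_["state"] = NumericVector(cur.begin(), cur.end()),
                      _["effector"] = cur[e],
                      _["steps"] = steps,
                      _["converged"] = converged);
}

// Infection episode on the parasite-augmented matrix. Checks, after every
// step and in this order: (a) step cap reached -> managed, (b) parasite
// below the clearance threshold -> cleared, (c) running normalized area
// above the death threshold -> host death.  Area is always normalized by
// max_steps.  outcome codes: 1 cleared, 2 managed, 3 host death.
// With early_stop = false the episode always runs max_steps and the
// outcome reflects the first condition that would have triggered.
// [[Rcpp::export(name = ".cpp_infection")]]
List cpp_infection(NumericMatrix W, NumericVector p0, double use_coef,
                   int eff_idx, int par_idx, double clearance_threshold,
                   double death_area_threshold, int max_steps,
                   bool early_stop) {
  int n = W.nrow();
  if (W.ncol() != n || p0.size() != n) stop("dimension mismatch");
  if (eff_idx < 1 || eff_idx > n || par_idx < 1 || par_idx > n)
    stop("node index out of range");
  std::vector<int> deg;
  out_degrees(W, deg);
  std::vector<double> cur(p0.begin(), p0.end()), nxt(n);
  int e = eff_idx - 1, q = par_idx - 1;
  std::vector<double> eff_trace, par_trace;
  eff_trace.reserve(max_steps);
  par_trace.reserve(max_steps);
  double par_sum = 0.0;
  int outcome = 0;
  for (int t = 1; t <= max_steps; ++t) {
    step_inplace(W, deg, use_coef, cur, nxt);
    cur.swap(nxt);
    eff_trace.push_back(cur[e]);
    par_trace.push_back(cur[q]);
    par_sum += cur[q];
    double area_run = par_sum / max_steps;
    if (outcome == 0) {
      if (t >= max_steps)                                outcome = 2;
      else if (cur[q] < clearance_threshold)             outcome = 1;
      else if (area_run > death_area_threshold)          outcome = 3;
    }
    if (outcome != 0 && early_stop) break;
  }
  if (outcome == 0) outcome = 2;
  return List::create(
      _["eff_trace"] = NumericVector(eff_trace.begin(), eff_trace.end()),
      _["par_trace"] = NumericVector(par_trace.begin(), par_trace.end()),
      _["outcome"] = outcome,
      _["area"] = par_sum / max_steps,
      _["state"] = NumericVector(cur.begin(), cur.end()));
}
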