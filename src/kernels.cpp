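#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Built-in toy-target log densities. id 1: isotropic normal, pars = (dim, sd).
// id 2: island mixture, pars = (n_islands, sd, barrier_depth); equally
// weighted narrow modes at unit spacing (centres 1..n) with the log-density
// valley between the outermost modes floored at barrier_depth below the
// peaks, so the barrier height is known by construction.
static double island_logdens(double x, int n, double sd, double barrier) {
  // log sum_k exp(-(x - k)^2 / (2 sd^2)) - log(n), via max-shift
  double best = R_NegInf;
  for (int k = 1; k <= n; ++k) {
    double z = (x - k) / sd;
    double t = -0.5 * z * z;
    if (t > best) best = t;
  }
  double acc = 0.0;
  for (int k = 1; k <= n; ++k) {
    double z = (x - k) / sd;
    acc += std::exp(-0.5 * z * z - best);
  }
  double ld = best + std::log(acc) - std::log((double)n);
  if (x >= 1.0 && x <= (double)n) {
    double floorv = -barrier - std::log((double)n);
    if (ld < floorv) ld = floorv;
  }
  return ld;
}

static double normal_logdens(NumericVector x, double sd) {
  double acc = 0.0;
  int d = x.size();
  for (int j = 0; j < d; ++j) acc += x[j] * x[j];
  return -0.5 * acc / (sd * sd) - d * (0.5 * std::log(2.0 * M_PI) + std::log(sd));
}

static double builtin_ld(NumericVector x, int id, NumericVector pars) {
  if (id == 1) return normal_logdens(x, pars[1]);
  if (id == 2) return island_logdens(x[0], (int)pars[0], pars[1], pars[2]);
  stop("unknown builtin target id");
  return NA_REAL; // not reached
}

// [[Rcpp::export]]
double builtin_logdens_cpp(NumericVector x, int id, NumericVector pars) {
  return builtin_ld(x, id, pars);
}

// Advance one chain for `nsteps` uniform-window random-walk Metropolis
// steps at temperature `beta`, using R's RNG (so the caller's per-chain RNG
// stream discipline applies). The proposal adds an independent
// Uniform(-w, w) perturbation to every coordinate (symmetric, zero Hastings
// correction); a uniform window needs one deviate per coordinate, which
// matters when a proposal touches hundreds of coordinates. Draw pattern per
// step: d window deviates, then one uniform for the accept decision.
// [[Rcpp::export]]
List advance_builtin_cpp(NumericVector x0, double ll0, double beta, int nsteps,
                         double halfwidth, int id, NumericVector pars) {
  RNGScope scope;
  int d = x0.size();
  NumericVector cur = clone(x0);
  NumericVector prop(d);
  double cll = ll0;
  int nacc = 0;
  for (int s = 0; s < nsteps; ++s) {
    for (int j = 0; j < d; ++j)
      prop[j] = cur[j] + (2.0 * unif_rand() - 1.0) * halfwidth;
    double pll = builtin_ld(prop, id, pars);
    double la = beta * (pll - cll);
    double u = unif_rand();
    if (la >= 0.0 || std::log(u) < la) {
      for (int j = 0; j < d; ++j) cur[j] = prop[j];
      cll = pll;
      ++nacc;
    }
  }
  return List::create(_["state"] = cur, _["log_likelihood"] = cll,
                      _["n_accept"] = nacc);
}
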