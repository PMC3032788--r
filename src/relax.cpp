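#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Explicit Euler integration of mass-action kinetics with source/sink flows.
//
// Reactions are given in compressed form: for reaction r, its substrate
// entries are positions sub_ptr[r] .. sub_ptr[r+1]-1 of (sub_idx, sub_mult),
// likewise for products. Rates must be direction-normalized (non-negative).
// Sinks lose mass at rate lambda * c; the total outflowing mass per unit
// time is fed back to the sources in proportion to inflow_share (shares sum
// to 1 over sources, 0 elsewhere), converted to concentration through the
// molecular mass, so total mass is conserved by construction.
//
// Integration stops at the first step where sum_i |c_i(t+dt) - c_i(t)| / dt
// falls below eps, or after max_steps.
// [[Rcpp::export]]
List relax_cpp(NumericVector conc0,
               IntegerVector sub_ptr, IntegerVector sub_idx, NumericVector sub_mult,
               IntegerVector prod_ptr, IntegerVector prod_idx, NumericVector prod_mult,
               NumericVector rate, NumericVector mass,
               IntegerVector sink_idx, NumericVector inflow_share,
               double lambda, double dt, double eps, int max_steps) {
  const int n = conc0.size();
  const int nr = rate.size();
  std::vector<double> c(conc0.begin(), conc0.end());
  std::vector<double> dc(n);
  const int* sp = sub_ptr.begin();
  const int* si = sub_idx.begin();
  const double* sm = sub_mult.begin();
  const int* pp = prod_ptr.begin();
  const int* pidx = prod_idx.begin();
  const double* pm = prod_mult.begin();
  const double* kr = rate.begin();
  const double* ms = mass.begin();
  const int n_sink = sink_idx.size();
  const int* snk = sink_idx.begin();
  // sources: precompute index list and per-source share/mass
  std::vector<int> src;
  std::vector<double> src_coef;
  for (int i = 0; i < n; ++i) {
    if (inflow_share[i] > 0.0) {
      src.push_back(i);
      src_coef.push_back(inflow_share[i] / mass[i]);
    }
  }
  bool converged = false, blowup = false;
  int step = 0;

  while (step < max_steps) {
    ++step;
    std::fill(dc.begin(), dc.end(), 0.0);

    for (int r = 0; r < nr; ++r) {
      double v = kr[r];
      if (v == 0.0) continue;
      const int s0 = sp[r], s1 = sp[r + 1];
      for (int p = s0; p < s1; ++p) {
        const double ci = c[si[p]];
        const double ml = sm[p];
        if (ml == 1.0)      v *= ci;
        else if (ml == 2.0) v *= ci * ci;
        else                v *= std::pow(ci, ml);
      }
      for (int p = s0; p < s1; ++p)
        dc[si[p]] -= sm[p] * v;
      const int p1 = pp[r + 1];
      for (int p = pp[r]; p < p1; ++p)
        dc[pidx[p]] += pm[p] * v;
    }

    double out_mass = 0.0;
    for (int k = 0; k < n_sink; ++k) {
      const int s = snk[k];
      out_mass += c[s] * ms[s];
      dc[s] -= lambda * c[s];
    }
    out_mass *= lambda;
    if (out_mass > 0.0) {
      for (size_t k = 0; k < src.size(); ++k)
        dc[src[k]] += src_coef[k] * out_mass;
    }

    double resid = 0.0;
    for (int i = 0; i < n; ++i) {
      double cn = c[i] + dt * dc[i];
      if (cn < 0.0) cn = 0.0;
      if (!std::isfinite(cn)) { blowup = true; break; }
      resid += std::fabs(cn - c[i]);
      c[i] = cn;
    }
    if (blowup) break;
    if (resid / dt < eps) { converged = true; break; }
    if (step % 16384 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["conc"] = NumericVector(c.begin(), c.end()),
    _["steps"] = step,
    _["converged"] = converged,
    _["blowup"] = blowup);
}
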