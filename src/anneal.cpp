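#include <Rcpp.h>
using namespace Rcpp;

// Penalty for unmet feature targets: sum_f spf_f * (shortfall_f/target_f) * G_f,
// where G_f is the cost of a greedy completion meeting feature f alone
// (computed once in R).  Zero iff every target is met.
static inline double penalty(const std::vector<double>& held,
                             const NumericVector& targets,
                             const NumericVector& spf,
                             const NumericVector& gcost) {
  double p = 0.0;
  for (int f = 0; f < (int)held.size(); ++f) {
    double short_f = targets[f] - held[f];
    if (short_f > 0.0) p += spf[f] * (short_f / targets[f]) * gcost[f];
  }
  return p;
}

// Simulated-annealing run over unit subsets.  Proposal: toggle one uniformly
// random non-locked unit; geometric cooling; uses R's RNG (seeded by the
// caller) so runs are reproducible.  Returns the best-seen state.
// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericVector cost, NumericMatrix amounts,
                NumericVector targets, NumericVector spf,
                NumericVector gcost, double blm,
                NumericVector perim,
                IntegerVector adj_ptr, IntegerVector adj_idx,
                NumericVector adj_len,
                LogicalVector locked, LogicalVector init,
                int iterations, double t_initial, double cooling) {
  const int n = cost.size();
  const int nf = targets.size();
  std::vector<int> cand;
  for (int i = 0; i < n; ++i) if (!locked[i]) cand.push_back(i);

  std::vector<int> sel(n);
  for (int i = 0; i < n; ++i) sel[i] = init[i] ? 1 : 0;

  std::vector<double> held(nf, 0.0);
  double cost_sum = 0.0, bl = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!sel[i]) continue;
    cost_sum += cost[i];
    for (int f = 0; f < nf; ++f) held[f] += amounts(i, f);
    bl += perim[i];
    for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k)
      if (sel[adj_idx[k]]) bl -= adj_len[k];  // each selected pair hit twice -> -2L total
  }
  double obj = cost_sum + blm * bl + penalty(held, targets, spf, gcost);

  // proposal delta for toggling unit j from the current state
  std::vector<double> held_new(nf);
  auto delta_of = [&](int j, double& d_bl_out) {
    int sign = sel[j] ? -1 : 1;
    double shared_sel = 0.0;
    for (int k = adj_ptr[j]; k < adj_ptr[j + 1]; ++k)
      if (sel[adj_idx[k]]) shared_sel += adj_len[k];
    double d_bl = sign * (perim[j] - 2.0 * shared_sel);
    for (int f = 0; f < nf; ++f) held_new[f] = held[f] + sign * amounts(j, f);
    double d = sign * cost[j] + blm * d_bl +
      penalty(held_new, targets, spf, gcost) -
      penalty(held, targets, spf, gcost);
    d_bl_out = d_bl;
    return d;
  };

  double t0 = t_initial;
  if (!(t0 > 0.0)) {  // auto: mean |delta| of 100 presampled moves
    double acc = 0.0; int m = 0;
    if (!cand.empty()) {
      for (int s = 0; s < 100; ++s) {
        int j = cand[(int)(unif_rand() * cand.size()) % cand.size()];
        double dbl_dummy;
        acc += std::fabs(delta_of(j, dbl_dummy));
        ++m;
      }
    }
    t0 = (m > 0 && acc > 0.0) ? acc / m : 1.0;
  }

  std::vector<int> best = sel;
  double best_obj = obj;
  double temp = t0;

  if (!cand.empty()) {
    for (int it = 0; it < iterations; ++it) {
      int j = cand[(int)(unif_rand() * cand.size()) % cand.size()];
      double d_bl;
      double d = delta_of(j, d_bl);
      if (d < 0.0 || unif_rand() < std::exp(-d / temp)) {
        int sign = sel[j] ? -1 : 1;
        sel[j] = 1 - sel[j];
        cost_sum += sign * cost[j];
        bl += d_bl;
        for (int f = 0; f < nf; ++f) held[f] = held_new[f];
        obj += d;
        if (obj < best_obj) { best_obj = obj; best = sel; }
      }
      temp *= cooling;
    }
  }

  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best[i] == 1;
  return List::create(_["selected"] = out, _["objective"] = best_obj);
}
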