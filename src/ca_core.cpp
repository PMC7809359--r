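#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Synchronous probabilistic cellular automaton on a fixed graph.
//
// State encoding per compartment:
//   0                  susceptible
//   refractory + 1     active (spiking this step)
//   1 .. refractory    refractory, value = steps left before susceptible
//
// All transitions are computed from the pre-step state vector. A susceptible
// compartment with k active neighbours and drive probability r becomes active
// with probability 1 - (1 - r) * (1 - P)^k (independent attempts). An active
// compartment enters the refractory stage; refractory compartments count
// down; a compartment leaving refractoriness is susceptible from the next
// step on, so the minimum inter-spike interval is refractory + 2 steps.
//
// adj/ptr: CSR adjacency (0-based); driven: per-compartment 0/1 flag for the
// external drive; occupancy: optionally tally post-update state codes over
// the counted steps. Uses R's RNG stream (seed it with set.seed upstream).

// [[Rcpp::export]]
List ca_simulate_core(IntegerVector adj, IntegerVector ptr, int n,
                      double P, double r, IntegerVector driven,
                      int refractory, int n_steps, int transient_steps,
                      bool occupancy) {
  const int active_code = refractory + 1;
  const double q = 1.0 - P;
  std::vector<int> s(n, 0), snew(n, 0);
  std::vector<double> spikes(n, 0.0);
  NumericMatrix occ(occupancy ? (refractory + 2) : 1,
                    occupancy ? n : 1);

  const int total = transient_steps + n_steps;
  for (int t = 0; t < total; ++t) {
    const bool counted = (t >= transient_steps);
    for (int i = 0; i < n; ++i) {
      const int si = s[i];
      if (si > 0) {
        snew[i] = si - 1;
      } else {
        int k = 0;
        for (int e = ptr[i]; e < ptr[i + 1]; ++e)
          if (s[adj[e]] == active_code) ++k;
        const double rr = driven[i] ? r : 0.0;
        double p;
        if (k == 0) {
          p = rr;
        } else {
          p = 1.0 - (1.0 - rr) * std::pow(q, (double)k);
        }
        if (p > 0.0 && unif_rand() < p) {
          snew[i] = active_code;
          if (counted) spikes[i] += 1.0;
        } else {
          snew[i] = 0;
        }
      }
      if (counted && occupancy) occ(snew[i], i) += 1.0;
    }
    std::swap(s, snew);
  }

  List out = List::create(_["spikes"] = NumericVector(spikes.begin(), spikes.end()),
                          _["n_counted_steps"] = n_steps);
  if (occupancy) out["occupancy"] = occ;
  return out;
}
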