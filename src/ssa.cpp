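#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Counter-based PRNG (splitmix64).  Each glycan gets an independent stream
// derived from (seed, glycan index), so profiles are bit-reproducible and
// independent of execution order.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t &s) {
  return ((splitmix64(s) >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// Gillespie simulation of n independent glycans over a compiled reaction
// network.  CSR layout: edges of state s are edge_ptr[s] .. edge_ptr[s+1]-1
// (0-based); per-edge propensity in cisterna c is
// rates(edge_enzyme[e], c) * edge_scale[e].
// [[Rcpp::export(name = ".ssa_run")]]
List ssa_run(IntegerVector edge_ptr, IntegerVector edge_to,
             IntegerVector edge_enzyme, NumericVector edge_scale,
             NumericMatrix rates, NumericVector residence,
             NumericVector input_cum, IntegerVector input_state,
             int n_glycans, double seed, bool record_events) {
  const int S = edge_ptr.size() - 1;
  const int E = edge_to.size();
  const int C = residence.size();

  // Per-cisterna edge propensities and per-state totals.
  std::vector<double> prop((size_t)E * C);
  std::vector<double> tot((size_t)S * C);
  for (int c = 0; c < C; ++c) {
    for (int e = 0; e < E; ++e)
      prop[(size_t)c * E + e] = rates(edge_enzyme[e], c) * edge_scale[e];
    for (int s = 0; s < S; ++s) {
      double t = 0.0;
      for (int e = edge_ptr[s]; e < edge_ptr[s + 1]; ++e)
        t += prop[(size_t)c * E + e];
      tot[(size_t)c * S + s] = t;
    }
  }

  IntegerVector final_state(n_glycans);
  std::vector<double> edge_counts((size_t)E * C, 0.0);
  std::vector<int> ev_glycan, ev_cisterna, ev_edge;
  std::vector<double> ev_time;

  const uint64_t base = (uint64_t)(int64_t)seed;
  for (int j = 0; j < n_glycans; ++j) {
    uint64_t rs = base * 0x9E3779B97F4A7C15ULL ^
                  ((uint64_t)(j + 1) * 0xD2B74407B1CE6E93ULL);
    splitmix64(rs); splitmix64(rs); // decorrelate nearby seeds

    double u = u01(rs);
    int k = 0;
    while (k + 1 < input_cum.size() && u > input_cum[k]) ++k;
    int state = input_state[k];

    for (int c = 0; c < C; ++c) {
      double clock = 0.0, T = residence[c];
      for (;;) {
        double R = tot[(size_t)c * S + state];
        if (R <= 0.0) break;
        double dt = -std::log(u01(rs)) / R;
        if (clock + dt >= T) break; // overshoot discarded at the deadline
        clock += dt;
        double r = u01(rs) * R, acc = 0.0;
        int chosen = edge_ptr[state + 1] - 1;
        for (int e = edge_ptr[state]; e < edge_ptr[state + 1]; ++e) {
          acc += prop[(size_t)c * E + e];
          if (r <= acc) { chosen = e; break; }
        }
        edge_counts[(size_t)c * E + chosen] += 1.0;
        if (record_events) {
          ev_glycan.push_back(j + 1);
          ev_cisterna.push_back(c + 1);
          ev_time.push_back(clock);
          ev_edge.push_back(chosen + 1);
        }
        state = edge_to[chosen];
      }
    }
    final_state[j] = state + 1;
  }

  NumericMatrix counts(E, C);
  for (int c = 0; c < C; ++c)
    for (int e = 0; e < E; ++e)
      counts(e, c) = edge_counts[(size_t)c * E + e];

  List out = List::create(_["final_state"] = final_state,
                          _["edge_counts"] = counts);
  if (record_events)
    out["events"] = List::create(_["glycan"] = wrap(ev_glycan),
                                 _["cisterna"] = wrap(ev_cisterna),
                                 _["time"] = wrap(ev_time),
                                 _["edge"] = wrap(ev_edge));
  return out;
}
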