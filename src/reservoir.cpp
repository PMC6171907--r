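#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-cycle local-reservoir simulator.
//
// Levels (0-based internally): lowers 0..N-1, uppers 0..N.
// Arrow ids: 0..N-1   = L_i (lower i -> upper i+1, Decision L)
//            N..2N-1  = R_i (lower i -> upper i,   Decision R)
// An arrow is available iff its source lower level is occupied and its
// target upper level is vacant.
//
// Each cycle: (1) recovery events scheduled for this cycle fire (vacant
// lower refills, occupied upper empties); (2) one of the 2N arrow slots is
// drawn uniformly; if that arrow is currently available it is executed,
// scheduling both recovery events at cycle + lifetime, otherwise the cycle
// yields no decision. Sampling slots rather than the available set keeps
// the decision timing stochastic; conditioning on the available set makes
// the recovery clocks phase-lock into near-periodic decision patterns for
// small reservoirs, which the model is not meant to show.
//
// All randomness comes from R's RNG (R::runif), so traces are reproducible
// with set.seed() and bit-identical to the pure-R reference stepper.

namespace {

struct Reservoir {
  int N, tau;
  std::vector<char> lower, upper;            // occupancy flags
  std::vector<int> avail;                    // ids of available arrows
  std::vector<int> pos;                      // pos[id] in avail, -1 if absent
  // recovery ring buffer: bucket[c % (tau+1)] holds events firing at cycle c
  // event encoding: i >= 0 -> refill lower i; i < 0 -> clear upper (-i - 1)
  std::vector<std::vector<int>> bucket;
  int cycle;

  Reservoir(int N_, int tau_) : N(N_), tau(tau_) {
    lower.assign(N, 1);
    upper.assign(N + 1, 0);
    pos.assign(2 * N, -1);
    avail.reserve(2 * N);
    for (int a = 0; a < 2 * N; ++a) push_avail(a);
    bucket.assign(tau + 1, std::vector<int>());
    cycle = 0;
  }

  inline int target_upper(int a) const { return a < N ? a + 1 : a - N; }
  inline int source_lower(int a) const { return a < N ? a : a - N; }

  inline void push_avail(int a) {
    if (pos[a] >= 0) return;
    pos[a] = (int)avail.size();
    avail.push_back(a);
  }
  inline void drop_avail(int a) {
    int p = pos[a];
    if (p < 0) return;
    int last = avail.back();
    avail[p] = last;
    pos[last] = p;
    avail.pop_back();
    pos[a] = -1;
  }
  inline void refresh_arrow(int a) {
    bool ok = lower[source_lower(a)] && !upper[target_upper(a)];
    if (ok) push_avail(a); else drop_avail(a);
  }
  // arrows touching lower i: L_i (id i) and R_i (id N+i)
  inline void refresh_lower(int i) { refresh_arrow(i); refresh_arrow(N + i); }
  // arrows targeting upper j: L_{j-1} (id j-1) and R_j (id N+j)
  inline void refresh_upper(int j) {
    if (j >= 1) refresh_arrow(j - 1);
    if (j < N) refresh_arrow(N + j);
  }

  inline void fire_recovery() {
    std::vector<int>& b = bucket[cycle % (tau + 1)];
    for (size_t k = 0; k < b.size(); ++k) {
      int ev = b[k];
      if (ev >= 0) { lower[ev] = 1; refresh_lower(ev); }
      else { int j = -ev - 1; upper[j] = 0; refresh_upper(j); }
    }
    b.clear();
  }

  // returns 0 = none, 1 = L, 2 = R; advances the cycle counter
  inline int choose_and_advance() {
    int decision = 0;
    int a = (int)(R::runif(0.0, 1.0) * (2 * N));
    if (a >= 2 * N) a = 2 * N - 1;
    if (pos[a] >= 0) {
      int i = source_lower(a), j = target_upper(a);
      decision = (a < N) ? 1 : 2;
      lower[i] = 0;
      upper[j] = 1;
      int when = cycle + tau;
      bucket[when % (tau + 1)].push_back(i);
      bucket[when % (tau + 1)].push_back(-j - 1);
      refresh_lower(i);
      refresh_upper(j);
    }
    ++cycle;
    return decision;
  }
};

// next decision (1/2) at or after each offset of d; 0 if none remains
inline void fill_next_decision(std::vector<int>& d) {
  for (int i = (int)d.size() - 2; i >= 0; --i)
    if (d[i] == 0) d[i] = d[i + 1];
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_run_trace(int n_levels, int lifetime, int n_cycles) {
  Reservoir res(n_levels, lifetime);
  IntegerVector out(n_cycles);
  for (int c = 0; c < n_cycles; ++c) {
    res.fire_recovery();
    out[c] = res.choose_and_advance();
  }
  return out;
}

// Monte Carlo consistency tally. With exact_readout (the default
// convention) the reference decision is the decision at cycle t0 itself
// and the lag-t decision the decision at cycle t0 + t, stalled cycles
// excluded; otherwise each is read from the first decision-bearing cycle
// at or after the nominal cycle. A (run, lag) pair with either decision
// missing is excluded. Also accumulates the active portion of arrows at
// cycle t0 (measured after recovery, before arrow selection).
// [[Rcpp::export]]
List cpp_consistency_mc(int n_levels, int lifetime, int t0, int max_lag,
                        int n_runs, int n_cycles, bool exact_readout) {
  std::vector<double> match(max_lag, 0.0), valid(max_lag, 0.0);
  double active_sum = 0.0;
  int tail_len = n_cycles - t0;
  std::vector<int> tail(tail_len);
  for (int r = 0; r < n_runs; ++r) {
    Reservoir res(n_levels, lifetime);
    for (int c = 0; c < n_cycles; ++c) {
      res.fire_recovery();
      if (c == t0)
        active_sum += (2.0 * n_levels - (double)res.avail.size()) /
                      (2.0 * n_levels);
      int d = res.choose_and_advance();
      if (c >= t0) tail[c - t0] = d;
    }
    if (!exact_readout) fill_next_decision(tail);
    int ref = tail[0];
    if (ref == 0) continue;
    for (int t = 1; t <= max_lag; ++t) {
      if (t >= tail_len) break;
      int d = tail[t];
      if (d == 0) continue;
      valid[t - 1] += 1.0;
      if (d == ref) match[t - 1] += 1.0;
    }
  }
  return List::create(_["match"] = wrap(match), _["valid"] = wrap(valid),
                      _["mean_active_portion"] = active_sum / n_runs);
}
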