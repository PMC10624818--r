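#include <Rcpp.h>
using namespace Rcpp;

// Synchronous threshold diffusion on a flattened adjacency structure.
// adj_flat holds 0-based neighbor indices; adj_ptr[i]..adj_ptr[i+1]-1 is
// the slice for unit i (adj_ptr has n+1 entries, 0-based offsets).
// States are absorbing; updates run for t = first_update_week..T against
// the previous week's states; a unit recovers when the fraction of
// recovered neighbors is >= its threshold (isolates have fraction 0).

static void step_states(const IntegerVector &adj_flat,
                        const IntegerVector &adj_ptr,
                        const NumericVector &tau,
                        std::vector<int> &state) {
  int n = tau.size();
  std::vector<int> prev(state);
  for (int i = 0; i < n; ++i) {
    if (prev[i]) continue;
    int lo = adj_ptr[i], hi = adj_ptr[i + 1];
    double frac = 0.0;
    if (hi > lo) {
      int c = 0;
      for (int k = lo; k < hi; ++k) c += prev[adj_flat[k]];
      frac = (double)c / (hi - lo);
    }
    if (frac >= tau[i]) state[i] = 1;
  }
}

// [[Rcpp::export]]
IntegerMatrix sim_trajectory_cpp(IntegerVector adj_flat, IntegerVector adj_ptr,
                                 NumericVector tau, IntegerVector seed_idx,
                                 int T, int first_update_week) {
  int n = tau.size();
  IntegerMatrix S(n, T + 1);
  std::vector<int> state(n, 0);
  for (int k = 0; k < seed_idx.size(); ++k) state[seed_idx[k]] = 1;
  for (int i = 0; i < n; ++i) S(i, 0) = state[i];
  for (int t = 1; t <= T; ++t) {
    if (t >= first_update_week) step_states(adj_flat, adj_ptr, tau, state);
    for (int i = 0; i < n; ++i) S(i, t) = state[i];
  }
  return S;
}

// 0-1 loss of a simulated run against an empirical trajectory, summed over
// t = 1..T (column 0 excluded); avoids materializing the trajectory.
// [[Rcpp::export]]
int sim_loss_cpp(IntegerVector adj_flat, IntegerVector adj_ptr,
                 NumericVector tau, IntegerVector seed_idx,
                 int T, int first_update_week, IntegerMatrix emp) {
  int n = tau.size();
  std::vector<int> state(n, 0);
  for (int k = 0; k < seed_idx.size(); ++k) state[seed_idx[k]] = 1;
  int loss = 0;
  for (int t = 1; t <= T; ++t) {
    if (t >= first_update_week) step_states(adj_flat, adj_ptr, tau, state);
    for (int i = 0; i < n; ++i)
      if (state[i] != emp(i, t)) ++loss;
  }
  return loss;
}

// Recovered count at the horizon T.
// [[Rcpp::export]]
int sim_recovered_cpp(IntegerVector adj_flat, IntegerVector adj_ptr,
                      NumericVector tau, IntegerVector seed_idx,
                      int T, int first_update_week) {
  int n = tau.size();
  std::vector<int> state(n, 0);
  for (int k = 0; k < seed_idx.size(); ++k) state[seed_idx[k]] = 1;
  for (int t = 1; t <= T; ++t)
    if (t >= first_update_week) step_states(adj_flat, adj_ptr, tau, state);
  int c = 0;
  for (int i = 0; i < n; ++i) c += state[i];
  return c;
}
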