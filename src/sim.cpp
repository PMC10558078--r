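#include <Rcpp.h>
using namespace Rcpp;

// Birth-death evolutionary dynamics on a hypergraph.
//
// Shared conventions: `edges` holds 0-based node indices per hyperedge,
// `incid` holds 0-based hyperedge indices per node. `state` is 0/1 per node
// (1 = mutant, fitness r; 0 = resident, fitness 1). Model 1 converts every
// co-member of the chosen hyperedge to the parent's type; model 2 does so
// only when strictly more than half of the hyperedge (parent included)
// already has the parent's type. Uses R's RNG stream (RNGScope), so results
// are reproducible under set.seed().

static int pick_parent(const std::vector<int>& state, int n_mut, double r) {
  int n = state.size();
  double total = r * n_mut + (n - n_mut);
  double u = unif_rand() * total;
  double acc = 0.0;
  for (int v = 0; v < n; ++v) {
    acc += state[v] ? r : 1.0;
    if (u < acc) return v;
  }
  return n - 1; // guard against round-off at the top end
}

// one update step in place; returns change in mutant count
static int do_step(const std::vector<std::vector<int>>& edges,
                   const std::vector<std::vector<int>>& incid,
                   std::vector<int>& state, int n_mut, int model, double r) {
  int v = pick_parent(state, n_mut, r);
  const std::vector<int>& ie = incid[v];
  int k = ie[(int)(unif_rand() * ie.size()) % ie.size()];
  const std::vector<int>& e = edges[k];
  int pt = state[v];
  if (model == 2) {
    int same = 0;
    for (int u : e) if (state[u] == pt) ++same;
    if (2 * same <= (int)e.size()) return 0; // parent's type not a strict majority
  }
  int delta = 0;
  for (int u : e) {
    if (state[u] != pt) {
      state[u] = pt;
      delta += pt ? 1 : -1;
    }
  }
  return delta;
}

static std::vector<std::vector<int>> as_vecvec(const List& x) {
  std::vector<std::vector<int>> out(x.size());
  for (int k = 0; k < x.size(); ++k) {
    IntegerVector v = x[k];
    out[k].assign(v.begin(), v.end());
  }
  return out;
}

// [[Rcpp::export(name = ".sim_step_cpp")]]
IntegerVector sim_step_cpp(List edges, List incid, IntegerVector state,
                           int model, double r) {
  RNGScope scope;
  auto E = as_vecvec(edges);
  auto I = as_vecvec(incid);
  std::vector<int> st(state.begin(), state.end());
  int n_mut = 0;
  for (int s : st) n_mut += s;
  do_step(E, I, st, n_mut, model, r);
  return IntegerVector(st.begin(), st.end());
}

// Run batches of independent realizations until fixation or max_steps.
// init: matrix with one 0/1 row per run (or a single row recycled).
// Returns per-run result code (1 mutant fixed, 0 resident fixed, -1 timeout)
// and step count.
// [[Rcpp::export(name = ".sim_runs_cpp")]]
List sim_runs_cpp(List edges, List incid, IntegerMatrix init, int n_runs,
                  int model, double r, double max_steps) {
  RNGScope scope;
  auto E = as_vecvec(edges);
  auto I = as_vecvec(incid);
  int N = init.ncol();
  IntegerVector result(n_runs);
  NumericVector steps(n_runs);
  for (int run = 0; run < n_runs; ++run) {
    int row = init.nrow() == 1 ? 0 : run;
    std::vector<int> st(N);
    int n_mut = 0;
    for (int v = 0; v < N; ++v) {
      st[v] = init(row, v);
      n_mut += st[v];
    }
    double t = 0.0;
    int code;
    while (true) {
      if (n_mut == 0) { code = 0; break; }
      if (n_mut == N) { code = 1; break; }
      if (t >= max_steps) { code = -1; break; }
      n_mut += do_step(E, I, st, n_mut, model, r);
      t += 1.0;
    }
    result[run] = code;
    steps[run] = t;
  }
  return List::create(_["result"] = result, _["steps"] = steps);
}
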