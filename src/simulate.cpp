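#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// A rule set is passed as two parallel lists over nodes (alphabetical order):
//   regs[i]: 0-based indices of node i's regulators, canonical (alphabetical) order
//   tts[i]:  truth table of length 2^k; row index = sum_p state[regs[p]] << p
//            (first regulator is the least-significant bit)
// clamp[i] in {-1, 0, 1}: -1 free, otherwise the node is pinned to that value.

typedef std::vector<std::vector<int>> IntVV;

static void unpack_rules(const List& regs, const List& tts, IntVV& r, IntVV& t) {
  int n = regs.size();
  r.resize(n);
  t.resize(n);
  for (int i = 0; i < n; ++i) {
    r[i] = as<std::vector<int>>(regs[i]);
    t[i] = as<std::vector<int>>(tts[i]);
  }
}

static inline void step_state(const std::vector<int>& s, std::vector<int>& out,
                              const IntVV& regs, const IntVV& tts,
                              const std::vector<int>& clamp) {
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) {
    if (clamp[i] >= 0) { out[i] = clamp[i]; continue; }
    const std::vector<int>& r = regs[i];
    int idx = 0;
    for (size_t p = 0; p < r.size(); ++p) idx |= s[r[p]] << p;
    out[i] = tts[i][idx];
  }
}

static inline std::string key_of(const std::vector<int>& s) {
  std::string k(s.size(), '0');
  for (size_t i = 0; i < s.size(); ++i) k[i] = s[i] ? '1' : '0';
  return k;
}

// Iterate from `start` until a state repeats; the repeated segment is the
// attractor (a fixed point when its length is 1). Returns the cycle states in
// trajectory order and whether a revisit occurred within max_steps.
static bool trajectory_cycle(std::vector<int> s, const IntVV& regs,
                             const IntVV& tts, const std::vector<int>& clamp,
                             int max_steps, std::vector<std::vector<int>>& cycle) {
  std::unordered_map<std::string, int> seen;
  std::vector<std::vector<int>> traj;
  traj.reserve(64);
  std::vector<int> nxt(s.size());
  for (int t = 0; t <= max_steps; ++t) {
    std::string k = key_of(s);
    std::unordered_map<std::string, int>::iterator it = seen.find(k);
    if (it != seen.end()) {
      cycle.assign(traj.begin() + it->second, traj.end());
      return true;
    }
    seen[k] = t;
    traj.push_back(s);
    step_state(s, nxt, regs, tts, clamp);
    s.swap(nxt);
  }
  // guard: budget exhausted without revisit; report last state as singleton
  cycle.assign(1, traj.back());
  return false;
}

static IntegerMatrix cycle_to_matrix(const std::vector<std::vector<int>>& cycle) {
  int L = (int)cycle.size(), n = (int)cycle[0].size();
  IntegerMatrix m(L, n);
  for (int a = 0; a < L; ++a)
    for (int j = 0; j < n; ++j) m(a, j) = cycle[a][j];
  return m;
}

// [[Rcpp::export]]
List cpp_attractor(IntegerVector start, List regs, List tts,
                   IntegerVector clamp, int max_steps) {
  IntVV r, t;
  unpack_rules(regs, tts, r, t);
  std::vector<int> s = as<std::vector<int>>(start);
  std::vector<int> cl = as<std::vector<int>>(clamp);
  // the clamp applies to the start state as well
  for (size_t i = 0; i < s.size(); ++i) if (cl[i] >= 0) s[i] = cl[i];
  std::vector<std::vector<int>> cycle;
  bool conv = trajectory_cycle(s, r, t, cl, max_steps, cycle);
  return List::create(_["states"] = cycle_to_matrix(cycle),
                      _["converged"] = conv);
}

// Batch attractor search over rows of `starts`, memoised on the start state.
// [[Rcpp::export]]
List cpp_attractors(IntegerMatrix starts, List regs, List tts,
                    IntegerVector clamp, int max_steps) {
  IntVV r, t;
  unpack_rules(regs, tts, r, t);
  std::vector<int> cl = as<std::vector<int>>(clamp);
  int nc = starts.nrow(), n = starts.ncol();
  std::unordered_map<std::string, int> memo; // start key -> index into out
  List out(nc);
  std::vector<int> s(n);
  for (int c = 0; c < nc; ++c) {
    for (int j = 0; j < n; ++j) {
      s[j] = starts(c, j);
      if (cl[j] >= 0) s[j] = cl[j];
    }
    std::string k = key_of(s);
    std::unordered_map<std::string, int>::iterator it = memo.find(k);
    if (it != memo.end()) { out[c] = out[it->second]; continue; }
    std::vector<std::vector<int>> cycle;
    trajectory_cycle(s, r, t, cl, max_steps, cycle);
    out[c] = cycle_to_matrix(cycle);
    memo[k] = c;
  }
  return out;
}

// Fitting errors for a full rule set against binarized cells E (cells x nodes).
// Each cell is simulated from its own state to its attractor T_c. Returns
//   total:    sum over cells of min_a sum_n |E_cn - A_cna|   (global error)
//   node_err: per node n, sum over cells of min_a |E_cn - A_cna| (local error)
// Identical cell rows are evaluated once and weighted by multiplicity.
// [[Rcpp::export]]
List cpp_eval_ruleset(IntegerMatrix E, List regs, List tts, int max_steps) {
  IntVV r, t;
  unpack_rules(regs, tts, r, t);
  int nc = E.nrow(), n = E.ncol();
  std::vector<int> cl(n, -1);
  std::unordered_map<std::string, int> counts;
  std::vector<std::string> order;
  for (int c = 0; c < nc; ++c) {
    std::string k(n, '0');
    for (int j = 0; j < n; ++j) k[j] = E(c, j) ? '1' : '0';
    if (counts.find(k) == counts.end()) order.push_back(k);
    counts[k]++;
  }
  double total = 0.0;
  NumericVector node_err(n);
  std::vector<int> s(n);
  for (size_t u = 0; u < order.size(); ++u) {
    const std::string& k = order[u];
    int w = counts[k];
    for (int j = 0; j < n; ++j) s[j] = k[j] == '1' ? 1 : 0;
    std::vector<std::vector<int>> cycle;
    trajectory_cycle(s, r, t, cl, max_steps, cycle);
    int best_sum = n + 1;
    std::vector<int> best_node(n, 2);
    for (size_t a = 0; a < cycle.size(); ++a) {
      int sum = 0;
      for (int j = 0; j < n; ++j) {
        int d = s[j] == cycle[a][j] ? 0 : 1;
        sum += d;
        if (d < best_node[j]) best_node[j] = d;
      }
      if (sum < best_sum) best_sum = sum;
    }
    total += (double)w * best_sum;
    for (int j = 0; j < n; ++j) node_err[j] += (double)w * best_node[j];
  }
  return List::create(_["total"] = total, _["node_err"] = node_err);
}

// Exhaustive attractor enumeration over all 2^n start states (test oracle).
// [[Rcpp::export]]
List cpp_enumerate_attractors(List regs, List tts, int max_steps) {
  IntVV r, t;
  unpack_rules(regs, tts, r, t);
  int n = regs.size();
  if (n > 20) stop("exhaustive enumeration limited to 20 nodes");
  std::vector<int> cl(n, -1);
  std::unordered_map<std::string, int> att_index; // canonical-ish key -> slot
  std::vector<IntegerMatrix> atts;
  std::vector<int> basin;
  long total = 1L << n;
  std::vector<int> s(n);
  for (long x = 0; x < total; ++x) {
    for (int j = 0; j < n; ++j) s[j] = (int)((x >> j) & 1L);
    std::vector<std::vector<int>> cycle;
    trajectory_cycle(s, r, t, cl, max_steps, cycle);
    // identify the cycle by its minimal state key (rotation invariant)
    std::string mink = key_of(cycle[0]);
    for (size_t a = 1; a < cycle.size(); ++a) {
      std::string k = key_of(cycle[a]);
      if (k < mink) mink = k;
    }
    std::unordered_map<std::string, int>::iterator it = att_index.find(mink);
    if (it == att_index.end()) {
      att_index[mink] = (int)atts.size();
      atts.push_back(cycle_to_matrix(cycle));
      basin.push_back(1);
    } else {
      basin[it->second]++;
    }
  }
  List states(atts.size());
  for (size_t i = 0; i < atts.size(); ++i) states[i] = atts[i];
  return List::create(_["states"] = states, _["basin"] = wrap(basin));
}
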