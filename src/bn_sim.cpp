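#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Flattened network layout shared by all entry points:
//   nreg[i]  — number of canalyzing tuples of gene i
//   off[i]   — start offset of gene i's tuples in reg/I/O (computed here)
//   reg[]    — 1-based regulator indices, converted to 0-based internally
//   I[], O[] — canalyzing / canalyzed bits per tuple
//   def[i]   — default output of gene i
// A clamp value of -1 means "free"; 0/1 pins the gene for the whole
// trajectory, initial state included.

struct FlatNet {
  int N;
  std::vector<int> off, reg, I, O, def, nreg;
};

static FlatNet unpack(const IntegerVector& nreg, const IntegerVector& reg,
                      const IntegerVector& I, const IntegerVector& O,
                      const IntegerVector& def) {
  FlatNet net;
  net.N = nreg.size();
  net.nreg.assign(nreg.begin(), nreg.end());
  net.off.resize(net.N + 1);
  net.off[0] = 0;
  for (int i = 0; i < net.N; ++i) net.off[i + 1] = net.off[i] + nreg[i];
  net.reg.resize(reg.size());
  for (int j = 0; j < reg.size(); ++j) net.reg[j] = reg[j] - 1;
  net.I.assign(I.begin(), I.end());
  net.O.assign(O.begin(), O.end());
  net.def.assign(def.begin(), def.end());
  return net;
}

static inline void step(const FlatNet& net, const std::vector<char>& s,
                        std::vector<char>& out, const std::vector<int>& clamp) {
  for (int i = 0; i < net.N; ++i) {
    if (clamp[i] >= 0) { out[i] = (char)clamp[i]; continue; }
    int val = net.def[i];
    for (int j = net.off[i]; j < net.off[i + 1]; ++j) {
      if (s[net.reg[j]] == net.I[j]) { val = net.O[j]; break; }
    }
    out[i] = (char)val;
  }
}

static inline std::string key_of(const std::vector<char>& s) {
  return std::string(s.begin(), s.end());
}

struct Traj {
  std::vector<std::vector<char>> cycle;  // attractor states in trajectory order
  int tau;
  bool truncated;
};

static Traj run_trajectory(const FlatNet& net, std::vector<char> s,
                           const std::vector<int>& clamp, int max_steps) {
  for (int i = 0; i < net.N; ++i) if (clamp[i] >= 0) s[i] = (char)clamp[i];
  std::unordered_map<std::string, int> seen;
  std::vector<std::vector<char>> traj;
  traj.reserve(64);
  Traj res;
  res.truncated = false;
  int t = 0;
  while (true) {
    std::string k = key_of(s);
    auto it = seen.find(k);
    if (it != seen.end()) {
      res.tau = it->second;
      for (int j = it->second; j < t; ++j) res.cycle.push_back(traj[j]);
      return res;
    }
    if (t > max_steps) {
      res.tau = t;
      res.truncated = true;
      res.cycle.push_back(s);
      return res;
    }
    seen.emplace(std::move(k), t);
    traj.push_back(s);
    std::vector<char> nxt(net.N);
    step(net, s, nxt, clamp);
    s.swap(nxt);
    ++t;
  }
}

static std::vector<int> clamp_vec(int N, const IntegerVector& cg,
                                  const IntegerVector& cv) {
  std::vector<int> clamp(N, -1);
  for (int j = 0; j < cg.size(); ++j)
    if (cg[j] >= 1) clamp[cg[j] - 1] = cv[j];
  return clamp;
}

static IntegerMatrix cycle_matrix(const std::vector<std::vector<char>>& cyc, int N) {
  IntegerMatrix m(cyc.size(), N);
  for (size_t r = 0; r < cyc.size(); ++r)
    for (int c = 0; c < N; ++c) m(r, c) = cyc[r][c];
  return m;
}

// [[Rcpp::export]]
List cpp_find_attractor(IntegerVector nreg, IntegerVector reg, IntegerVector I,
                        IntegerVector O, IntegerVector def, IntegerVector init,
                        IntegerVector clamp_gene, IntegerVector clamp_val,
                        int max_steps) {
  FlatNet net = unpack(nreg, reg, I, O, def);
  std::vector<char> s(init.begin(), init.end());
  std::vector<int> clamp = clamp_vec(net.N, clamp_gene, clamp_val);
  Traj tr = run_trajectory(net, s, clamp, max_steps);
  return List::create(_["states"] = cycle_matrix(tr.cycle, net.N),
                      _["tau"] = tr.tau,
                      _["period"] = (int)tr.cycle.size(),
                      _["truncated"] = tr.truncated);
}

// Per-experiment dynamics similarity: each row of `inits` is simulated under
// its row's clamp; s_i is the per-gene agreement of `observed` with the
// attractor cycle (truncated runs score against the final state only).
// [[Rcpp::export]]
List cpp_dynamics(IntegerVector nreg, IntegerVector reg, IntegerVector I,
                  IntegerVector O, IntegerVector def, IntegerMatrix inits,
                  IntegerVector clamp_gene, IntegerVector clamp_val,
                  IntegerMatrix observed, int max_steps) {
  FlatNet net = unpack(nreg, reg, I, O, def);
  int E = inits.nrow(), N = net.N;
  NumericVector per_exp(E);
  NumericMatrix s_gene(E, N);
  LogicalVector trunc(E);
  for (int e = 0; e < E; ++e) {
    std::vector<char> s(N);
    for (int i = 0; i < N; ++i) s[i] = (char)inits(e, i);
    std::vector<int> clamp(N, -1);
    if (clamp_gene[e] >= 1) clamp[clamp_gene[e] - 1] = clamp_val[e];
    Traj tr = run_trajectory(net, s, clamp, max_steps);
    trunc[e] = tr.truncated;
    int p = tr.cycle.size();
    double tot = 0.0;
    for (int i = 0; i < N; ++i) {
      int match = 0;
      for (int t = 0; t < p; ++t)
        if (tr.cycle[t][i] == observed(e, i)) ++match;
      double si = (double)match / p;
      s_gene(e, i) = si;
      tot += si;
    }
    per_exp[e] = tot / N;
  }
  return List::create(_["per_experiment"] = per_exp, _["s_gene"] = s_gene,
                      _["truncated"] = trunc);
}

// Bulk attractor collection from many initial states under one clamp set.
// Attractors are canonicalized by rotating the cycle to start at its
// lexicographically smallest state, and returned with basin counts.
// [[Rcpp::export]]
List cpp_collect_attractors(IntegerVector nreg, IntegerVector reg, IntegerVector I,
                            IntegerVector O, IntegerVector def,
                            IntegerMatrix inits, IntegerVector clamp_gene,
                            IntegerVector clamp_val, int max_steps) {
  FlatNet net = unpack(nreg, reg, I, O, def);
  int M = inits.nrow(), N = net.N;
  std::vector<int> clamp = clamp_vec(N, clamp_gene, clamp_val);
  std::unordered_map<std::string, int> index;
  std::vector<std::vector<std::vector<char>>> atts;
  std::vector<bool> att_trunc;
  std::vector<int> counts;
  IntegerVector assignment(M);
  for (int m = 0; m < M; ++m) {
    std::vector<char> s(N);
    for (int i = 0; i < N; ++i) s[i] = (char)inits(m, i);
    Traj tr = run_trajectory(net, s, clamp, max_steps);
    int p = tr.cycle.size();
    int best = 0;
    for (int t = 1; t < p; ++t)
      if (key_of(tr.cycle[t]) < key_of(tr.cycle[best])) best = t;
    std::vector<std::vector<char>> canon;
    for (int t = 0; t < p; ++t) canon.push_back(tr.cycle[(best + t) % p]);
    std::string k = tr.truncated ? "T:" : "C:";
    for (auto& st : canon) k += key_of(st);
    auto it = index.find(k);
    int idx;
    if (it == index.end()) {
      idx = atts.size();
      index.emplace(k, idx);
      atts.push_back(canon);
      att_trunc.push_back(tr.truncated);
      counts.push_back(0);
    } else idx = it->second;
    counts[idx] += 1;
    assignment[m] = idx + 1;
  }
  List states(atts.size());
  for (size_t a = 0; a < atts.size(); ++a) states[a] = cycle_matrix(atts[a], N);
  return List::create(_["states"] = states,
                      _["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["truncated"] = LogicalVector(att_trunc.begin(), att_trunc.end()),
                      _["assignment"] = assignment);
}
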