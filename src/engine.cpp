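// Synchronous Boolean network engine: state stepping, attractor detection,
// exhaustive and sampled landscape construction with trajectory memoization.
//
// States are held as std::string over {'0','1'} in node order; rules are
// postfix programs with tokens >= 0 (variable index), -1 NOT, -2 AND,
// -3 OR, -4 constant 0, -5 constant 1.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::vector<std::vector<int> > Prog;

static Prog as_prog(const List &progs) {
  Prog out(progs.size());
  for (int i = 0; i < progs.size(); ++i) {
    IntegerVector p = progs[i];
    out[i].assign(p.begin(), p.end());
  }
  return out;
}

// one synchronous step; pinned nodes (pin >= 0) take their pinned value
static void step_state(const Prog &prog, const std::vector<int> &pin,
                       const std::string &s, std::string &out) {
  const int n = (int)prog.size();
  std::vector<char> stack;
  stack.reserve(16);
  for (int i = 0; i < n; ++i) {
    if (pin[i] >= 0) { out[i] = (char)('0' + pin[i]); continue; }
    const std::vector<int> &p = prog[i];
    stack.clear();
    for (size_t t = 0; t < p.size(); ++t) {
      const int tok = p[t];
      if (tok >= 0) stack.push_back(s[tok] == '1');
      else if (tok == -1) stack.back() = !stack.back();
      else if (tok == -2) { char a = stack.back(); stack.pop_back(); stack.back() = (stack.back() && a); }
      else if (tok == -3) { char a = stack.back(); stack.pop_back(); stack.back() = (stack.back() || a); }
      else if (tok == -4) stack.push_back(0);
      else stack.push_back(1);
    }
    out[i] = (char)('0' + (int)stack.back());
  }
}

struct Engine {
  Prog prog;
  std::vector<int> pin;
  std::unordered_map<std::string, int> memo;         // state -> attractor index
  std::vector<std::vector<std::string> > cycles;     // canonical cycles

  Engine(const List &progs, const IntegerVector &pins)
    : prog(as_prog(progs)), pin(pins.begin(), pins.end()) {}

  // walk a trajectory; returns attractor index, fills transient length
  int trajectory(std::string s, int *transient = 0) {
    std::vector<std::string> path;
    std::unordered_map<std::string, int> onpath;
    int attr = -1;
    for (;;) {
      std::unordered_map<std::string, int>::iterator it = memo.find(s);
      if (it != memo.end()) { attr = it->second; if (transient) *transient = -1; break; }
      std::unordered_map<std::string, int>::iterator jt = onpath.find(s);
      if (jt != onpath.end()) {
        // closed a new cycle: path[jt->second .. end]
        std::vector<std::string> cyc(path.begin() + jt->second, path.end());
        size_t mi = 0;
        for (size_t k = 1; k < cyc.size(); ++k) if (cyc[k] < cyc[mi]) mi = k;
        std::rotate(cyc.begin(), cyc.begin() + mi, cyc.end());
        cycles.push_back(cyc);
        attr = (int)cycles.size() - 1;
        if (transient) *transient = jt->second;
        break;
      }
      onpath[s] = (int)path.size();
      path.push_back(s);
      std::string nx(s);
      step_state(prog, pin, s, nx);
      s.swap(nx);
    }
    for (size_t k = 0; k < path.size(); ++k) memo[path[k]] = attr;
    return attr;
  }
};

static IntegerMatrix cycle_matrix(const std::vector<std::string> &cyc) {
  const int L = (int)cyc.size(), n = (int)cyc[0].size();
  IntegerMatrix m(L, n);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < n; ++j)
      m(i, j) = cyc[i][j] == '1';
  return m;
}

static List cycles_list(const std::vector<std::vector<std::string> > &cycles) {
  List out(cycles.size());
  for (size_t a = 0; a < cycles.size(); ++a) out[a] = cycle_matrix(cycles[a]);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_step(List progs, IntegerVector pins, IntegerVector state) {
  Prog prog = as_prog(progs);
  std::vector<int> pin(pins.begin(), pins.end());
  const int n = (int)prog.size();
  std::string s(n, '0'), nx(n, '0');
  for (int i = 0; i < n; ++i) s[i] = (char)('0' + state[i]);
  step_state(prog, pin, s, nx);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = nx[i] == '1';
  return out;
}

// [[Rcpp::export]]
List cpp_evolve(List progs, IntegerVector pins, IntegerVector state) {
  Engine eng(progs, pins);
  const int n = (int)eng.prog.size();
  std::string s(n, '0');
  for (int i = 0; i < n; ++i) s[i] = (char)('0' + state[i]);
  int transient = 0;
  int attr = eng.trajectory(s, &transient);
  return List::create(_["cycle"] = cycle_matrix(eng.cycles[attr]),
                      _["transient"] = transient);
}

// [[Rcpp::export]]
List cpp_enumerate(List progs, IntegerVector pins) {
  Engine eng(progs, pins);
  const int n = (int)eng.prog.size();
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) if (pins[i] < 0) free_idx.push_back(i);
  const int f = (int)free_idx.size();
  if (f > 30) stop("free-node space too large to enumerate");
  const double total = std::pow(2.0, f);
  std::string base(n, '0');
  for (int i = 0; i < n; ++i) if (pins[i] >= 0) base[i] = (char)('0' + pins[i]);
  std::vector<double> counts;
  for (double idx = 0; idx < total; idx += 1.0) {
    unsigned long v = (unsigned long)idx;
    std::string s(base);
    for (int j = 0; j < f; ++j) s[free_idx[j]] = (char)('0' + ((v >> j) & 1UL));
    int attr = eng.trajectory(s);
    if ((size_t)attr >= counts.size()) counts.resize(attr + 1, 0.0);
    counts[attr] += 1.0;
  }
  return List::create(_["cycles"] = cycles_list(eng.cycles),
                      _["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["total"] = total);
}

// [[Rcpp::export]]
List cpp_sample(List progs, IntegerVector pins, int n_samples) {
  Engine eng(progs, pins);
  const int n = (int)eng.prog.size();
  std::vector<int> free_idx;
  for (int i = 0; i < n; ++i) if (pins[i] < 0) free_idx.push_back(i);
  std::string base(n, '0');
  for (int i = 0; i < n; ++i) if (pins[i] >= 0) base[i] = (char)('0' + pins[i]);
  std::vector<double> counts;
  for (int k = 0; k < n_samples; ++k) {
    std::string s(base);
    for (size_t j = 0; j < free_idx.size(); ++j)
      s[free_idx[j]] = unif_rand() < 0.5 ? '0' : '1';
    int attr = eng.trajectory(s);
    if ((size_t)attr >= counts.size()) counts.resize(attr + 1, 0.0);
    counts[attr] += 1.0;
  }
  return List::create(_["cycles"] = cycles_list(eng.cycles),
                      _["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["total"] = (double)n_samples);
}

// evolve each supplied initial state; return per-run attractor mean activity
// [[Rcpp::export]]
NumericMatrix cpp_run_batch(List progs, IntegerVector pins, IntegerMatrix inits) {
  Engine eng(progs, pins);
  const int n = (int)eng.prog.size();
  const int R = inits.nrow();
  NumericMatrix out(R, n);
  std::vector<std::vector<double> > act;  // cached per-attractor mean activity
  for (int r = 0; r < R; ++r) {
    std::string s(n, '0');
    for (int i = 0; i < n; ++i) s[i] = (char)('0' + inits(r, i));
    int attr = eng.trajectory(s);
    if ((size_t)attr >= act.size()) act.resize(eng.cycles.size());
    if (act[attr].empty()) {
      const std::vector<std::string> &cyc = eng.cycles[attr];
      std::vector<double> m(n, 0.0);
      for (size_t i = 0; i < cyc.size(); ++i)
        for (int j = 0; j < n; ++j) m[j] += cyc[i][j] == '1';
      for (int j = 0; j < n; ++j) m[j] /= (double)cyc.size();
      act[attr] = m;
    }
    for (int j = 0; j < n; ++j) out(r, j) = act[attr][j];
  }
  return out;
}
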