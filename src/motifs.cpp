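#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Triads are classified only when the induced 3-node subgraph is connected,
// has 2 or 3 unidirectional edges, and contains no reciprocal pair. Any
// triad with >= 4 edges necessarily contains a reciprocal pair, so valid
// triads have exactly the edges enumerated below.

typedef long long ekey;
static inline ekey key_of(int u, int v, int n) {
  return (ekey)u * (ekey)n + (ekey)v;
}

struct Net {
  int n;
  std::vector<std::vector<int> > out, in;
  std::unordered_set<ekey> edges;
  Net(int n_, const IntegerVector& from, const IntegerVector& to)
      : n(n_), out(n_), in(n_) {
    int m = from.size();
    edges.reserve(m * 2);
    for (int e = 0; e < m; ++e) {
      int u = from[e] - 1, v = to[e] - 1;
      out[u].push_back(v);
      in[v].push_back(u);
      edges.insert(key_of(u, v, n));
    }
  }
  bool has(int u, int v) const {
    return edges.count(key_of(u, v, n)) > 0;
  }
  bool recip(int u, int v) const { return has(u, v) && has(v, u); }
};

// [[Rcpp::export]]
IntegerVector census5_cpp(int n, IntegerVector from, IntegerVector to) {
  Net g(n, from, to);
  long long ffl = 0, cascade = 0, fan_in = 0, fan_out = 0, cycle3 = 0;

  // 3-edge classes, anchored on one edge
  for (std::unordered_set<ekey>::const_iterator it = g.edges.begin();
       it != g.edges.end(); ++it) {
    int u = (int)(*it / g.n), v = (int)(*it % g.n);
    if (g.has(v, u)) continue;  // reciprocal anchor
    // FFL: u -> v -> t with u -> t (u master, v intermediate, t target)
    const std::vector<int>& ov = g.out[v];
    for (size_t k = 0; k < ov.size(); ++k) {
      int t = ov[k];
      if (t == u) continue;
      if (g.has(u, t) && !g.has(t, v) && !g.has(t, u)) ++ffl;
      // cycle: u -> v -> t -> u (each cycle found 3 times)
      if (g.has(t, u) && !g.has(u, t) && !g.has(t, v)) ++cycle3;
    }
  }
  cycle3 /= 3;

  // 2-edge classes
  for (int b = 0; b < n; ++b) {
    // cascade a -> b -> c
    for (size_t i = 0; i < g.in[b].size(); ++i) {
      int a = g.in[b][i];
      if (g.has(b, a)) continue;
      for (size_t j = 0; j < g.out[b].size(); ++j) {
        int c = g.out[b][j];
        if (c == a || g.has(c, b)) continue;
        if (!g.has(a, c) && !g.has(c, a)) ++cascade;
      }
    }
    // fan-out: b -> {x, y}, no edge between x and y
    std::vector<int> nb;
    for (size_t i = 0; i < g.out[b].size(); ++i)
      if (!g.has(g.out[b][i], b)) nb.push_back(g.out[b][i]);
    for (size_t i = 0; i < nb.size(); ++i)
      for (size_t j = i + 1; j < nb.size(); ++j)
        if (!g.has(nb[i], nb[j]) && !g.has(nb[j], nb[i])) ++fan_out;
    // fan-in: {x, y} -> b
    nb.clear();
    for (size_t i = 0; i < g.in[b].size(); ++i)
      if (!g.has(b, g.in[b][i])) nb.push_back(g.in[b][i]);
    for (size_t i = 0; i < nb.size(); ++i)
      for (size_t j = i + 1; j < nb.size(); ++j)
        if (!g.has(nb[i], nb[j]) && !g.has(nb[j], nb[i])) ++fan_in;
  }

  IntegerVector res = IntegerVector::create(
      _["ffl"] = (double)ffl, _["cascade"] = (double)cascade,
      _["fan_in"] = (double)fan_in, _["fan_out"] = (double)fan_out,
      _["cycle"] = (double)cycle3);
  return res;
}

// All FFL instances as (master, intermediate, target) rows, 1-based.
// [[Rcpp::export]]
IntegerMatrix ffl_list_cpp(int n, IntegerVector from, IntegerVector to) {
  Net g(n, from, to);
  std::vector<int> mm, ii, tt;
  for (std::unordered_set<ekey>::const_iterator it = g.edges.begin();
       it != g.edges.end(); ++it) {
    int u = (int)(*it / g.n), v = (int)(*it % g.n);
    if (g.has(v, u)) continue;
    const std::vector<int>& ov = g.out[v];
    for (size_t k = 0; k < ov.size(); ++k) {
      int t = ov[k];
      if (t == u) continue;
      if (g.has(u, t) && !g.has(t, v) && !g.has(t, u)) {
        mm.push_back(u + 1);
        ii.push_back(v + 1);
        tt.push_back(t + 1);
      }
    }
  }
  IntegerMatrix res(mm.size(), 3);
  for (size_t r = 0; r < mm.size(); ++r) {
    res(r, 0) = mm[r];
    res(r, 1) = ii[r];
    res(r, 2) = tt[r];
  }
  colnames(res) = CharacterVector::create("master", "intermediate", "target");
  return res;
}

// Degree-preserving randomization by directed double-edge swaps:
// (a->b, c->d) => (a->d, c->b), rejecting self-loops and duplicates.
// Runs until at least min_frac of the ORIGINAL edges are absent from the
// current edge set, or the attempt budget is exhausted. Uses R's RNG.
// [[Rcpp::export]]
List swap_shuffle_cpp(int n, IntegerVector from, IntegerVector to,
                      double min_frac, double max_attempts) {
  int m = from.size();
  std::vector<int> ef(m), et(m);
  std::unordered_set<ekey> cur, orig;
  cur.reserve(m * 2);
  orig.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    ef[e] = from[e] - 1;
    et[e] = to[e] - 1;
    ekey k = key_of(ef[e], et[e], n);
    cur.insert(k);
    orig.insert(k);
  }
  int orig_present = m;
  int need_absent = (int)std::ceil(min_frac * m - 1e-9);
  double attempts = 0;
  while (m - orig_present < need_absent && attempts < max_attempts) {
    ++attempts;
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = ef[i], b = et[i], c = ef[j], d = et[j];
    if (a == d || c == b) continue;            // would create self-loop
    if (b == d || a == c) continue;            // no-op rewiring
    if (cur.count(key_of(a, d, n)) || cur.count(key_of(c, b, n))) continue;
    // apply swap
    cur.erase(key_of(a, b, n));
    cur.erase(key_of(c, d, n));
    if (orig.count(key_of(a, b, n))) --orig_present;
    if (orig.count(key_of(c, d, n))) --orig_present;
    et[i] = d;
    et[j] = b;
    cur.insert(key_of(a, d, n));
    cur.insert(key_of(c, b, n));
    if (orig.count(key_of(a, d, n))) ++orig_present;
    if (orig.count(key_of(c, b, n))) ++orig_present;
  }
  IntegerVector rf(m), rt(m);
  for (int e = 0; e < m; ++e) {
    rf[e] = ef[e] + 1;
    rt[e] = et[e] + 1;
  }
  double achieved = m > 0 ? 1.0 - (double)orig_present / m : 1.0;
  return List::create(_["from"] = rf, _["to"] = rt,
                      _["frac_swapped"] = achieved);
}
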