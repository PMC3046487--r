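// Degree-preserving randomization of a simple undirected graph.
//
// Primary scheme: stub matching -- cut every edge into two half-edges,
// shuffle, rematch; reject and restart whenever the matching produces a
// self-loop or multi-edge, so accepted samples are uniform over simple
// realizations of the degree sequence.  If `max_restarts` matchings fail
// (heavy-tailed degree sequences make collisions likely), fall back to a
// double-edge-swap Markov chain seeded from the observed graph, run for
// `swap_factor * |E|` accepted swaps.  Both schemes preserve every
// vertex's exact degree.
//
// All randomness flows through R's RNG (unif_rand), so set.seed() on the
// R side makes results reproducible.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

static inline long long edge_key(int a, int b, int n) {
  int lo = a < b ? a : b;
  int hi = a < b ? b : a;
  return static_cast<long long>(lo) * n + hi;
}

static inline int runif_int(int n) {
  // uniform on {0, ..., n-1}
  int k = static_cast<int>(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// One stub-matching attempt. Returns true and fills `out` on success.
static bool stub_match_once(const std::vector<int>& stubs, int n_vertices,
                            std::vector<int>& scratch,
                            std::vector<std::pair<int, int> >& out) {
  const int n_stub = static_cast<int>(stubs.size());
  const int m = n_stub / 2;
  scratch.assign(stubs.begin(), stubs.end());
  for (int i = n_stub - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    std::swap(scratch[i], scratch[j]);
  }
  std::unordered_set<long long> seen;
  seen.reserve(static_cast<size_t>(m) * 2);
  out.clear();
  for (int e = 0; e < m; ++e) {
    int a = scratch[2 * e], b = scratch[2 * e + 1];
    if (a == b) return false;
    if (!seen.insert(edge_key(a, b, n_vertices)).second) return false;
    out.push_back(std::make_pair(std::min(a, b), std::max(a, b)));
  }
  return true;
}

// Double-edge-swap MCMC starting from `edges`; mutates in place.
// Returns the number of accepted swaps.
static int double_edge_swap(std::vector<std::pair<int, int> >& edges,
                            int n_vertices, int target_swaps) {
  const int m = static_cast<int>(edges.size());
  if (m < 2) return 0;
  std::unordered_set<long long> present;
  present.reserve(static_cast<size_t>(m) * 2);
  for (int e = 0; e < m; ++e)
    present.insert(edge_key(edges[e].first, edges[e].second, n_vertices));
  int accepted = 0;
  long long attempts = 0;
  const long long max_attempts = 200LL * target_swaps + 1000LL;
  while (accepted < target_swaps && attempts < max_attempts) {
    ++attempts;
    int e1 = runif_int(m), e2 = runif_int(m);
    if (e1 == e2) continue;
    int a = edges[e1].first, b = edges[e1].second;
    int c = edges[e2].first, d = edges[e2].second;
    // orientation coin: (a,b),(c,d) -> (a,d),(c,b)  or  (a,c),(d,b)
    if (unif_rand() < 0.5) std::swap(c, d);
    int na1 = a, nb1 = d, na2 = c, nb2 = b;
    if (na1 == nb1 || na2 == nb2) continue;
    long long k1 = edge_key(na1, nb1, n_vertices);
    long long k2 = edge_key(na2, nb2, n_vertices);
    if (k1 == k2) continue;
    if (present.count(k1) || present.count(k2)) continue;
    present.erase(edge_key(edges[e1].first, edges[e1].second, n_vertices));
    present.erase(edge_key(edges[e2].first, edges[e2].second, n_vertices));
    present.insert(k1);
    present.insert(k2);
    edges[e1] = std::make_pair(std::min(na1, nb1), std::max(na1, nb1));
    edges[e2] = std::make_pair(std::min(na2, nb2), std::max(na2, nb2));
    ++accepted;
  }
  return accepted;
}

static void collect_stubs(const IntegerMatrix& edges, std::vector<int>& stubs) {
  const int m = edges.nrow();
  stubs.clear();
  stubs.reserve(2 * m);
  for (int e = 0; e < m; ++e) {
    stubs.push_back(edges(e, 0));
    stubs.push_back(edges(e, 1));
  }
}

static void rewire_core(const IntegerMatrix& edges, int n_vertices,
                        int max_restarts, int swap_factor,
                        std::vector<std::pair<int, int> >& out,
                        std::string& method) {
  const int m = edges.nrow();
  std::vector<int> stubs, scratch;
  collect_stubs(edges, stubs);
  for (int r = 0; r < max_restarts; ++r) {
    if (stub_match_once(stubs, n_vertices, scratch, out)) {
      method = "stub";
      return;
    }
  }
  out.clear();
  out.reserve(m);
  for (int e = 0; e < m; ++e)
    out.push_back(std::make_pair(edges(e, 0), edges(e, 1)));
  int target = swap_factor * m;
  int acc = double_edge_swap(out, n_vertices, target);
  method = (acc >= target) ? "swap" : "swap_incomplete";
}

//' @noRd
// [[Rcpp::export(name = ".cpp_rewire")]]
List cpp_rewire(IntegerMatrix edges, int n_vertices, int max_restarts = 100,
                int swap_factor = 10) {
  std::vector<std::pair<int, int> > out;
  std::string method;
  rewire_core(edges, n_vertices, max_restarts, swap_factor, out, method);
  const int m = static_cast<int>(out.size());
  IntegerMatrix res(m, 2);
  for (int e = 0; e < m; ++e) {
    res(e, 0) = out[e].first;
    res(e, 1) = out[e].second;
  }
  return List::create(_["edges"] = res, _["method"] = method);
}

// Index of unordered group pair (g1 <= g2) among G*(G+1)/2 cells.
static inline int pair_index(int g1, int g2, int G) {
  if (g1 > g2) std::swap(g1, g2);
  return g1 * G - g1 * (g1 - 1) / 2 + (g2 - g1);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_null_group_counts")]]
List cpp_null_group_counts(IntegerMatrix edges, IntegerVector labels,
                           int n_vertices, int n_groups, int n_random,
                           int max_restarts = 100, int swap_factor = 10) {
  const int n_pairs = n_groups * (n_groups + 1) / 2;
  IntegerMatrix counts(n_pairs, n_random);
  CharacterVector methods(n_random);
  std::vector<std::pair<int, int> > sample;
  std::string method;
  for (int s = 0; s < n_random; ++s) {
    rewire_core(edges, n_vertices, max_restarts, swap_factor, sample, method);
    methods[s] = method;
    for (size_t e = 0; e < sample.size(); ++e) {
      int g1 = labels[sample[e].first];
      int g2 = labels[sample[e].second];
      counts(pair_index(g1, g2, n_groups), s) += 1;
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["counts"] = counts, _["methods"] = methods);
}
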