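#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving double-edge swaps (Maslov-Sneppen) on an undirected
// edge list; each edge keeps its weight, so the weight multiset and the
// degree sequence are both invariant. Uses R's RNG so results follow
// set.seed(). edges: m x 2 integer matrix, 1-based node ids, i != j.
// [[Rcpp::export(name = ".ms_rewire_cpp")]]
IntegerMatrix ms_rewire_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
  int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [n_nodes](int u, int v) {
    if (u > v) std::swap(u, v);
    return (long long)u * (n_nodes + 1) + v;
  };
  for (int e = 0; e < m; e++) {
    ea[e] = edges(e, 0);
    eb[e] = edges(e, 1);
    present.insert(key(ea[e], eb[e]));
  }
  GetRNGstate();
  for (int t = 0; t < n_attempts; t++) {
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed: (a,d) and (c,b)
    if (a == d || c == b) continue;
    if (key(a, d) == key(c, b)) continue;
    if (present.count(key(a, d)) || present.count(key(c, b))) continue;
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(key(a, d));
    present.insert(key(c, b));
    eb[e1] = d;
    eb[e2] = b;
    ea[e2] = c;
  }
  PutRNGstate();
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; e++) { out(e, 0) = ea[e]; out(e, 1) = eb[e]; }
  return out;
}
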