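#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge-swap randomization.
//
// Edges arrive as a canonical list: strictly directed edges and undirected
// edges (one row each; an undirected edge occupies both orientations of its
// pair). Swaps are proposed separately within the two classes, the class
// picked per attempt in proportion to class size. A proposal is rejected if
// it would create a self-loop or duplicate any existing directed pair
// (undirected edges block both orientations). In- and out-degrees are
// preserved exactly by construction.
//
// Uses R's RNG so set.seed() on the R side makes the result reproducible.

static inline long long pkey(int a, int b, int n) {
  return (long long)a * (long long)n + (long long)b;
}

// [[Rcpp::export]]
List rewire_edges_cpp(IntegerVector src, IntegerVector tgt,
                      LogicalVector undirected, int n_nodes, int n_attempts) {
  int ne = src.size();
  std::vector<int> s(src.begin(), src.end());
  std::vector<int> t(tgt.begin(), tgt.end());
  std::vector<int> dir_idx, und_idx;
  for (int i = 0; i < ne; ++i) {
    if (undirected[i]) und_idx.push_back(i); else dir_idx.push_back(i);
  }
  std::unordered_set<long long> pairs;
  pairs.reserve(ne * 3);
  for (int i = 0; i < ne; ++i) {
    pairs.insert(pkey(s[i], t[i], n_nodes));
    if (undirected[i]) pairs.insert(pkey(t[i], s[i], n_nodes));
  }
  int nd = dir_idx.size(), nu = und_idx.size();
  double p_dir = (nd + nu > 0) ? (double)nd / (nd + nu) : 0.0;
  bool can_dir = nd >= 2, can_und = nu >= 2;
  int accepted = 0;

  for (int a = 0; a < n_attempts; ++a) {
    bool do_dir = unif_rand() < p_dir;
    if (do_dir && !can_dir) continue;
    if (!do_dir && !can_und) continue;
    if (do_dir) {
      int i = dir_idx[(int)(unif_rand() * nd)];
      int j = dir_idx[(int)(unif_rand() * nd)];
      if (i == j) continue;
      int a1 = s[i], b1 = t[i], a2 = s[j], b2 = t[j];
      if (b1 == b2 || a1 == a2) continue;        // swap is a no-op
      if (a1 == b2 || a2 == b1) continue;        // would create self-loop
      long long k1 = pkey(a1, b2, n_nodes), k2 = pkey(a2, b1, n_nodes);
      if (pairs.count(k1) || pairs.count(k2)) continue;
      pairs.erase(pkey(a1, b1, n_nodes));
      pairs.erase(pkey(a2, b2, n_nodes));
      pairs.insert(k1); pairs.insert(k2);
      t[i] = b2; t[j] = b1;
      ++accepted;
    } else {
      int i = und_idx[(int)(unif_rand() * nu)];
      int j = und_idx[(int)(unif_rand() * nu)];
      if (i == j) continue;
      int a1 = s[i], b1 = t[i], a2 = s[j], b2 = t[j];
      if (unif_rand() < 0.5) std::swap(a2, b2);  // unbiased pairing choice
      // proposed: a1-b2, a2-b1
      if (a1 == b2 || a2 == b1) continue;        // self-loop
      long long k1a = pkey(a1, b2, n_nodes), k1b = pkey(b2, a1, n_nodes);
      long long k2a = pkey(a2, b1, n_nodes), k2b = pkey(b1, a2, n_nodes);
      if (pairs.count(k1a) || pairs.count(k1b) ||
          pairs.count(k2a) || pairs.count(k2b)) continue;
      pairs.erase(pkey(a1, b1, n_nodes)); pairs.erase(pkey(b1, a1, n_nodes));
      pairs.erase(pkey(a2, b2, n_nodes)); pairs.erase(pkey(b2, a2, n_nodes));
      pairs.insert(k1a); pairs.insert(k1b);
      pairs.insert(k2a); pairs.insert(k2b);
      t[i] = b2; s[j] = a2; t[j] = b1;
      ++accepted;
    }
  }
  return List::create(_["source"] = wrap(s), _["target"] = wrap(t),
                      _["accepted"] = accepted);
}
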