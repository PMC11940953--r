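#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Deterministic generator independent of R's RNG so that walk corpora and
// skip-gram training are bit-reproducible for a given seed across platforms.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  uint64_t nextInt(uint64_t n) { return next() % n; }
  double nextDouble() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// [[Rcpp::export(name = ".cppSimulateWalks")]]
List cppSimulateWalks(List adj, int walksPerNode, int walkLength,
                      double seed) {
  int n = adj.size();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = adj[i];
    nb[i] = std::vector<int>(v.begin(), v.end());
  }
  XorShift rng((uint64_t)seed);
  List out(n * walksPerNode);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int w = 0;
  std::vector<int> walk;
  walk.reserve(walkLength);
  for (int pass = 0; pass < walksPerNode; ++pass) {
    // Fisher-Yates shuffle of start nodes per pass
    for (int i = n - 1; i > 0; --i) {
      int j = (int)rng.nextInt((uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int k = 0; k < n; ++k) {
      int cur = order[k];
      walk.clear();
      walk.push_back(cur);
      for (int step = 1; step < walkLength; ++step) {
        const std::vector<int>& cnb = nb[cur];
        if (cnb.empty()) break;  // dead end: truncate the walk
        cur = cnb[rng.nextInt(cnb.size())];
        walk.push_back(cur);
      }
      out[w++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}
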