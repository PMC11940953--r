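#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Skip-gram with negative sampling over a walk corpus, in the style of the
// reference word2vec trainer: dynamic context window, unigram^0.75 negative
// table, linearly decaying learning rate. Single-threaded on purpose so a
// fixed seed gives bit-identical embeddings.

namespace {

struct XorShift64 {
  uint64_t s;
  explicit XorShift64(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  uint64_t nextInt(uint64_t n) { return next() % n; }
  double nextDouble() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

const int NEG_TABLE_SIZE = 1000000;

inline double fastSigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = ".cppTrainSgns")]]
NumericMatrix cppTrainSgns(List walks, int nNodes, int dim, int window,
                           int negative, int epochs, double alpha,
                           double seed) {
  int nWalks = walks.size();
  std::vector<std::vector<int> > corpus(nWalks);
  std::vector<double> counts(nNodes, 0.0);
  long long totalWords = 0;
  for (int i = 0; i < nWalks; ++i) {
    IntegerVector v = walks[i];
    corpus[i] = std::vector<int>(v.begin(), v.end());
    for (size_t j = 0; j < corpus[i].size(); ++j) counts[corpus[i][j]] += 1.0;
    totalWords += corpus[i].size();
  }

  // unigram^0.75 table for negative sampling
  std::vector<int> negTable(NEG_TABLE_SIZE);
  double z = 0.0;
  for (int i = 0; i < nNodes; ++i) z += std::pow(counts[i], 0.75);
  {
    int i = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int t = 0; t < NEG_TABLE_SIZE; ++t) {
      negTable[t] = i;
      if ((double)t / NEG_TABLE_SIZE > cum && i < nNodes - 1) {
        ++i;
        cum += std::pow(counts[i], 0.75) / z;
      }
    }
  }

  XorShift64 rng((uint64_t)seed);
  std::vector<double> syn0((size_t)nNodes * dim);
  std::vector<double> syn1((size_t)nNodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.nextDouble() - 0.5) / dim;

  const double minAlphaFrac = 1e-4;
  long long trained = 0;
  long long totalTrain = (long long)epochs * totalWords;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int wi = 0; wi < nWalks; ++wi) {
      const std::vector<int>& walk = corpus[wi];
      int len = (int)walk.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha *
            (1.0 - (double)trained / (double)(totalTrain + 1));
        if (lr < alpha * minAlphaFrac) lr = alpha * minAlphaFrac;
        ++trained;
        int reduced = (int)rng.nextInt((uint64_t)window);
        int lo = pos - window + reduced;
        int hi = pos + window - reduced;
        if (lo < 0) lo = 0;
        if (hi >= len) hi = len - 1;
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          int center = walk[cpos];   // word whose input vector is updated
          double* v0 = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = walk[pos];
              label = 1.0;
            } else {
              target = negTable[rng.nextInt(NEG_TABLE_SIZE)];
              if (target == walk[pos]) continue;
              label = 0.0;
            }
            double* v1 = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v0[d] * v1[d];
            double g = (label - fastSigmoid(dot)) * lr;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v1[d];
              v1[d] += g * v0[d];
            }
          }
          for (int d = 0; d < dim; ++d) v0[d] += grad[d];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(nNodes, dim);
  for (int i = 0; i < nNodes; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return out;
}
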