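// Skip-gram with negative sampling over a random-walk corpus.
// Single-threaded, own xorshift RNG -> bit-reproducible for a fixed seed
// on one platform. Mirrors the classic word2vec training loop: dynamic
// context window, unigram^0.75 negative-sampling table, linearly decaying
// learning rate.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0, n)
  uint64_t bounded(uint64_t n) { return next() % n; }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// walks: list of integer vectors with 1-based node indices (1..V)
// returns V x dim matrix of input vectors
// [[Rcpp::export(rng = false)]]
NumericMatrix sgns_train(List walks, int vocab_size, int dim, int window,
                         int epochs, int negative, double alpha0,
                         double alpha_min, int seed) {
  const int V = vocab_size;
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // flatten corpus
  std::vector<std::vector<int>> corpus;
  corpus.reserve(walks.size());
  std::vector<double> counts(V, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < walks.size(); ++i) {
    IntegerVector w = walks[i];
    std::vector<int> ww(w.size());
    for (int j = 0; j < w.size(); ++j) {
      ww[j] = w[j] - 1;
      counts[ww[j]] += 1.0;
    }
    total_tokens += w.size();
    corpus.push_back(std::move(ww));
  }
  if (total_tokens == 0) stop("empty walk corpus");

  // negative sampling table, unigram^0.75
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    std::vector<double> pw(V);
    for (int v = 0; v < V; ++v) {
      pw[v] = std::pow(counts[v], 0.75);
      z += pw[v];
    }
    if (z <= 0) stop("no walked nodes");
    int v = 0;
    double cum = pw[0] / z;
    for (int t = 0; t < table_size; ++t) {
      table[t] = v;
      if ((t + 1.0) / table_size > cum && v < V - 1) {
        ++v;
        cum += pw[v] / z;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> neu1e(dim);
  const long long total_steps =
      static_cast<long long>(epochs) * total_tokens;
  long long done = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t wi = 0; wi < corpus.size(); ++wi) {
      const std::vector<int>& sent = corpus[wi];
      const int n = static_cast<int>(sent.size());
      for (int pos = 0; pos < n; ++pos) {
        double alpha = alpha0 * (1.0 - static_cast<double>(done) / total_steps);
        if (alpha < alpha_min) alpha = alpha_min;
        ++done;
        const int center = sent[pos];
        const int b = static_cast<int>(rng.bounded(static_cast<uint64_t>(window)));
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          const int cpos = pos + off;
          if (cpos < 0 || cpos >= n) continue;
          const int context = sent[cpos];
          double* v_in = &syn0[static_cast<size_t>(context) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.bounded(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            const double g = (label - sigmoid(f)) * alpha;
            for (int k = 0; k < dim; ++k) {
              neu1e[k] += g * v_out[k];
              v_out[k] += g * v_in[k];
            }
          }
          for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int k = 0; k < dim; ++k) out(v, k) = syn0[static_cast<size_t>(v) * dim + k];
  return out;
}
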