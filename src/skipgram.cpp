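#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline double unif01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);
}

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// Skip-gram with negative sampling over a corpus of 0-based token sequences.
// Single-threaded and seeded so training is exactly reproducible. Returns the
// input-vector matrix (vocab_size x d). Negatives are drawn from the unigram
// distribution raised to 3/4. Learning rate decays linearly to min_alpha.
// [[Rcpp::export(name = ".skipgram_cpp")]]
NumericMatrix skipgram_cpp(List sequences, int vocab_size, int d, int window,
                           int negatives, int epochs, double alpha,
                           double min_alpha, double seed) {
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));

  // unigram^0.75 cumulative table for negative sampling
  std::vector<double> freq(vocab_size, 0.0);
  std::size_t total_tokens = 0;
  const int n_seq = sequences.size();
  for (int s = 0; s < n_seq; ++s) {
    IntegerVector sq = sequences[s];
    total_tokens += sq.size();
    for (int i = 0; i < sq.size(); ++i) freq[sq[i]] += 1.0;
  }
  std::vector<double> cum(vocab_size, 0.0);
  double acc = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    acc += std::pow(freq[v], 0.75);
    cum[v] = acc;
  }

  // syn0 (input) small uniform init, syn1 (output) zeros, word2vec convention
  std::vector<double> syn0(static_cast<std::size_t>(vocab_size) * d);
  std::vector<double> syn1(static_cast<std::size_t>(vocab_size) * d, 0.0);
  for (std::size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / d;

  std::vector<double> neu1e(d);
  const double total_work =
      static_cast<double>(total_tokens) * epochs;
  double done = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_seq; ++s) {
      IntegerVector sq = sequences[s];
      const int len = sq.size();
      for (int pos = 0; pos < len; ++pos) {
        done += 1.0;
        const double lr =
            std::max(min_alpha, alpha * (1.0 - done / (total_work + 1.0)));
        const int center = sq[pos];
        double *v_in = &syn0[static_cast<std::size_t>(center) * d];
        const int lo = std::max(0, pos - window);
        const int hi = std::min(len - 1, pos + window);
        for (int cpos = lo; cpos <= hi; ++cpos) {
          if (cpos == pos) continue;
          const int ctx = sq[cpos];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negatives; ++k) {
            int target;
            double label;
            if (k == 0) {
              target = ctx;
              label = 1.0;
            } else {
              const double u = unif01(rng) * acc;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v_out = &syn1[static_cast<std::size_t>(target) * d];
            double f = 0.0;
            for (int j = 0; j < d; ++j) f += v_in[j] * v_out[j];
            const double g = (label - sigmoid(f)) * lr;
            for (int j = 0; j < d; ++j) neu1e[j] += g * v_out[j];
            for (int j = 0; j < d; ++j) v_out[j] += g * v_in[j];
          }
          for (int j = 0; j < d; ++j) v_in[j] += neu1e[j];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, d);
  for (int v = 0; v < vocab_size; ++v)
    for (int j = 0; j < d; ++j)
      out(v, j) = syn0[static_cast<std::size_t>(v) * d + j];
  return out;
}
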