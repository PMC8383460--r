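// Skip-gram with negative sampling over precomputed (center, context)
// pairs. Single-threaded, deterministic: all randomness comes from an
// internal xorshift generator seeded by the caller.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t state;
  explicit XorShift(uint64_t seed) : state(seed ? seed : 88172645463325252ULL) {}
  uint64_t next() {
    state ^= state << 13;
    state ^= state >> 7;
    state ^= state << 17;
    return state;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export(name = "sgns_train")]]
NumericMatrix sgns_train(IntegerVector centers, IntegerVector contexts,
                         int vocab_size, int dim, NumericVector counts,
                         int epochs, int negative, double lr, int seed,
                         NumericVector init) {
  const R_xlen_t n_pairs = centers.size();
  std::vector<double> in(vocab_size * (size_t)dim);
  std::vector<double> out(vocab_size * (size_t)dim, 0.0);
  for (size_t i = 0; i < in.size(); ++i) in[i] = init[i];

  // unigram^0.75 negative-sampling table (cumulative distribution)
  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int v = 0; v < vocab_size; ++v) {
    tot += std::pow(counts[v], 0.75);
    cum[v] = tot;
  }

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> grad(dim);

  const double total_steps = (double)epochs * (double)n_pairs;
  double step = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (R_xlen_t p = 0; p < n_pairs; ++p, step += 1.0) {
      const double alpha = lr * std::max(1.0 - step / total_steps, 1e-4);
      const int c = centers[p], x = contexts[p];
      double* vin = &in[(size_t)c * dim];
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int k = 0; k <= negative; ++k) {
        int target;
        double label;
        if (k == 0) {
          target = x;
          label = 1.0;
        } else {
          double u = rng.unif() * tot;
          target = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                         cum.begin());
          if (target >= vocab_size) target = vocab_size - 1;
          if (target == x) continue;
          label = 0.0;
        }
        double* vout = &out[(size_t)target * dim];
        double dot = 0.0;
        for (int j = 0; j < dim; ++j) dot += vin[j] * vout[j];
        const double g = (label - sigmoid(dot)) * alpha;
        for (int j = 0; j < dim; ++j) {
          grad[j] += g * vout[j];
          vout[j] += g * vin[j];
        }
      }
      for (int j = 0; j < dim; ++j) vin[j] += grad[j];
    }
  }

  NumericMatrix res(vocab_size, dim);
  for (int v = 0; v < vocab_size; ++v)
    for (int j = 0; j < dim; ++j) res(v, j) = in[(size_t)v * dim + j];
  return res;
}
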