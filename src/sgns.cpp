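#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// xorshift64* PRNG: keeps training independent of R's RNG stream and
// bit-reproducible across platforms for a given seed.
static inline uint64_t xs_next(uint64_t &s) {
  s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
  return s * 0x2545F4914F6CDD1DULL;
}
static inline double xs_unif(uint64_t &s) {
  return (xs_next(s) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer-coded sentences.
// sentences: list of integer vectors with 1-based token ids in 1..vocab.
// counts: token frequencies (unigram^(3/4) negative-sampling table).
// Returns vocab x dim matrix of input vectors.
// [[Rcpp::export(name = ".sgns_train_cpp")]]
NumericMatrix sgns_train_cpp(List sentences, int vocab, int dim, int window,
                             int negative, int epochs, double lr,
                             NumericVector counts, double seed) {
  if (vocab < 1 || dim < 1) stop("vocab and dim must be >= 1");
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (rng == 0) rng = 88172645463325252ULL;

  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (xs_unif(rng) - 0.5) / dim;

  // cumulative unigram^0.75 table for negative sampling
  std::vector<double> cum(vocab);
  double tot = 0.0;
  for (int v = 0; v < vocab; ++v) {
    tot += std::pow(std::max(counts[v], 0.0), 0.75);
    cum[v] = tot;
  }
  if (tot <= 0) stop("all token counts are zero");

  long long total_tokens = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_tokens += ((IntegerVector)sentences[s]).size();
  long long steps_total = (long long)epochs * std::max(total_tokens, 1LL);
  long long step = 0;

  std::vector<double> grad(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      int n = sent.size();
      for (int t = 0; t < n; ++t, ++step) {
        double alpha = lr * (1.0 - (double)step / (double)(steps_total + 1));
        if (alpha < lr * 1e-4) alpha = lr * 1e-4;
        int centre = sent[t] - 1;
        if (centre < 0 || centre >= vocab) continue;
        // reduced window, as in the reference word2vec implementation
        int b = 1 + (int)(xs_unif(rng) * window);
        if (b > window) b = window;
        for (int off = -b; off <= b; ++off) {
          if (off == 0) continue;
          int tc = t + off;
          if (tc < 0 || tc >= n) continue;
          int ctx = sent[tc] - 1;
          if (ctx < 0 || ctx >= vocab) continue;
          double *v_in = &syn0[(size_t)ctx * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target; double label;
            if (neg == 0) { target = centre; label = 1.0; }
            else {
              double r = xs_unif(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == centre) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v_in[d] * v_out[d];
            double g = (label - sigmoid(dot)) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_out[d];
              v_out[d] += g * v_in[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_in[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int v = 0; v < vocab; ++v)
    for (int d = 0; d < dim; ++d) out(v, d) = syn0[(size_t)v * dim + d];
  return out;
}
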