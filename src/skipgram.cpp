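#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Deterministic 64-bit LCG (word2vec's constants) so results are
// reproducible for a fixed seed independent of R's RNG state.
static inline uint64_t next_rand(uint64_t &r) {
  r = r * 25214903917ULL + 11ULL;
  return r;
}

static inline double urand(uint64_t &r) {
  next_rand(r);
  return ((r >> 16) & 0xFFFFFFFFULL) / 4294967296.0;
}

// Skip-gram with negative sampling over integer-coded sentences.
// sentences: list of 0-based integer vectors; unigram_weights: sampling
// weights per vocabulary id (counts^0.75 upstream). Returns the input
// (center-word) vectors, vocab_size x dim.
// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(List sentences, int vocab_size, int dim,
                             int window, int epochs, int negative,
                             double alpha0, double alpha_min,
                             NumericVector unigram_weights, int seed) {
  if (vocab_size < 1 || dim < 1 || window < 1 || epochs < 1)
    stop("vocab_size, dim, window and epochs must all be >= 1");

  std::vector<double> cum(vocab_size);
  double tot = 0.0;
  for (int i = 0; i < vocab_size; ++i) {
    tot += unigram_weights[i];
    cum[i] = tot;
  }
  if (!(tot > 0)) stop("unigram weights must have positive sum");

  std::vector< std::vector<int> > corpus;
  long long total_words = 0;
  for (R_xlen_t s = 0; s < sentences.size(); ++s) {
    IntegerVector sv = sentences[s];
    if (sv.size() == 0) continue;
    for (R_xlen_t j = 0; j < sv.size(); ++j)
      if (sv[j] < 0 || sv[j] >= vocab_size) stop("token id out of range");
    corpus.push_back(std::vector<int>(sv.begin(), sv.end()));
    total_words += sv.size();
  }
  if (total_words == 0) stop("empty corpus: no non-empty sentence supplied");

  uint64_t rng = static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL;
  size_t nsyn = static_cast<size_t>(vocab_size) * dim;
  std::vector<double> syn0(nsyn), syn1(nsyn, 0.0);
  for (size_t i = 0; i < nsyn; ++i)
    syn0[i] = (urand(rng) - 0.5) / dim;

  long long processed = 0;
  const long long total = total_words * (long long)epochs;
  std::vector<double> grad(dim);

  for (int e = 0; e < epochs; ++e) {
    for (size_t si = 0; si < corpus.size(); ++si) {
      const std::vector<int> &sent = corpus[si];
      int n = (int)sent.size();
      for (int i = 0; i < n; ++i) {
        double alpha = alpha0 * (1.0 - (double)processed / (double)(total + 1));
        if (alpha < alpha_min) alpha = alpha_min;
        ++processed;
        // dynamic window: effective half-width uniform in 1..window
        next_rand(rng);
        int b = (int)((rng >> 16) % (uint64_t)window);
        int lo = i - (window - b), hi = i + (window - b);
        for (int j = lo; j <= hi; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          int w = sent[i], ctx = sent[j];
          double *v = &syn0[(size_t)w * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int d2 = 0; d2 <= negative; ++d2) {
            int target, label;
            if (d2 == 0) {
              target = ctx; label = 1;
            } else {
              double u = urand(rng) * tot;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                             cum.begin());
              if (target >= vocab_size) target = vocab_size - 1;
              if (target == ctx) continue;
              label = 0;
            }
            double *o = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d3 = 0; d3 < dim; ++d3) f += v[d3] * o[d3];
            double sig = 1.0 / (1.0 + std::exp(-f));
            double g = (label - sig) * alpha;
            for (int d3 = 0; d3 < dim; ++d3) {
              grad[d3] += g * o[d3];
              o[d3] += g * v[d3];
            }
          }
          for (int d3 = 0; d3 < dim; ++d3) v[d3] += grad[d3];
        }
      }
    }
    for (size_t i = 0; i < nsyn; ++i)
      if (!std::isfinite(syn0[i]))
        stop("non-finite vector component after epoch %d", e + 1);
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int d3 = 0; d3 < dim; ++d3)
      out(i, d3) = syn0[(size_t)i * dim + d3];
  return out;
}
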