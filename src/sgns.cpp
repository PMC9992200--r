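// Skip-gram with negative sampling (word2vec-style), single-threaded and
// fully deterministic for a fixed seed.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic across platforms, unlike R's RNG streams
// consumed from C++.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

const int TABLE_SIZE = 1 << 20;
const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

}  // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List sentences, int vocab_size,
                         IntegerVector vocab_count, int dim, int window,
                         int epochs, int negative, double alpha, int seed) {
  if (dim < 1) stop("dim must be >= 1");
  if (window < 1) stop("window must be >= 1");
  if (epochs < 1) stop("epochs must be >= 1");

  // Unigram^0.75 negative-sampling table.
  std::vector<int> table(TABLE_SIZE);
  double train_words_pow = 0.0;
  const double power = 0.75;
  for (int a = 0; a < vocab_size; ++a)
    train_words_pow += std::pow((double)vocab_count[a], power);
  int i = 0;
  double d1 = std::pow((double)vocab_count[0], power) / train_words_pow;
  for (int a = 0; a < TABLE_SIZE; ++a) {
    table[a] = i;
    if ((double)a / TABLE_SIZE > d1 && i < vocab_size - 1) {
      ++i;
      d1 += std::pow((double)vocab_count[i], power) / train_words_pow;
    }
  }

  // Precomputed sigmoid table.
  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int a = 0; a < EXP_TABLE_SIZE; ++a) {
    double e = std::exp((a / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[a] = e / (e + 1.0);
  }

  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);

  std::vector<double> syn0((size_t)vocab_size * dim);
  std::vector<double> syn1((size_t)vocab_size * dim, 0.0);
  for (size_t a = 0; a < syn0.size(); ++a)
    syn0[a] = (rng.unif() - 0.5) / dim;

  long long total_words = 0;
  int n_sent = sentences.size();
  for (int s = 0; s < n_sent; ++s)
    total_words += Rf_length(VECTOR_ELT(sentences, s));
  long long train_total = total_words * (long long)epochs;
  if (train_total < 1) stop("empty corpus");

  std::vector<double> neu1e(dim);
  long long word_count = 0;
  const double min_alpha = alpha * 1e-4;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < n_sent; ++s) {
      IntegerVector sen = sentences[s];
      int slen = sen.size();
      for (int pos = 0; pos < slen; ++pos) {
        double lr = alpha * (1.0 - (double)word_count / (train_total + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++word_count;
        int word = sen[pos];
        int b = (int)(rng.next() % (uint64_t)window);  // dynamic window
        for (int a = b; a < window * 2 + 1 - b; ++a) {
          if (a == window) continue;
          int c = pos - window + a;
          if (c < 0 || c >= slen) continue;
          int last_word = sen[c];
          double *v_in = &syn0[(size_t)last_word * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = word;
              label = 1.0;
            } else {
              target = table[rng.next() % TABLE_SIZE];
              if (target == word) continue;
              label = 0.0;
            }
            double *v_out = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            double g;
            if (f > MAX_EXP) g = (label - 1.0) * lr;
            else if (f < -MAX_EXP) g = label * lr;
            else {
              int ei = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              g = (label - expTable[ei]) * lr;
            }
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int a = 0; a < vocab_size; ++a)
    for (int k = 0; k < dim; ++k) out(a, k) = syn0[(size_t)a * dim + k];
  return out;
}
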