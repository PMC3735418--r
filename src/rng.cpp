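#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Reproducible MT19937 stream. std::mt19937 implements the reference
// Mersenne Twister exactly (the C++ standard fixes the 10000th output of a
// default-seeded generator at 4123659995), so sequences are bit-identical
// across platforms. Doubles use the 53-bit construction of genrand_res53.

// [[Rcpp::export]]
SEXP mt_create_(int seed) {
  XPtr<std::mt19937> p(new std::mt19937(static_cast<uint32_t>(seed)), true);
  return p;
}

// [[Rcpp::export]]
NumericVector mt_u32_(SEXP rng, int n) {
  XPtr<std::mt19937> p(rng);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = static_cast<double>((*p)());
  return out;
}

// [[Rcpp::export]]
NumericVector mt_unif_(SEXP rng, int n) {
  XPtr<std::mt19937> p(rng);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t a = (*p)() >> 5, b = (*p)() >> 6;
    out[i] = (a * 67108864.0 + b) * (1.0 / 9007199254740992.0);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector mt_int_(SEXP rng, int n, int k) {
  XPtr<std::mt19937> p(rng);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t a = (*p)() >> 5, b = (*p)() >> 6;
    double u = (a * 67108864.0 + b) * (1.0 / 9007199254740992.0);
    out[i] = 1 + static_cast<int>(u * k);
  }
  return out;
}
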