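// Additive secret sharing over the ring Z_{2^64} with fixed-point
// encoding. R has no native 64-bit integers, so ring elements cross the
// R/C++ boundary packed as pairs of doubles holding the high and low
// 32-bit words: a length-n tensor becomes a length-2n numeric vector
// (hi_1, lo_1, hi_2, lo_2, ...). All modular arithmetic stays in C++.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <random>

using namespace Rcpp;

static inline uint64_t unpack_word(const double *p) {
  return (static_cast<uint64_t>(p[0]) << 32) | static_cast<uint64_t>(p[1]);
}

static inline void pack_word(double *p, uint64_t w) {
  p[0] = static_cast<double>(w >> 32);
  p[1] = static_cast<double>(w & 0xFFFFFFFFULL);
}

// encode a real to the ring: round(x * 2^f) in two's complement
static inline uint64_t fp_encode_one(double x, int f) {
  long double scaled = static_cast<long double>(x) * std::pow(2.0L, f);
  if (std::fabs(static_cast<double>(scaled)) > 4.6e18) {
    stop("value overflows the fixed-point range");
  }
  long long v = llroundl(scaled);
  return static_cast<uint64_t>(v);
}

static inline double fp_decode_one(uint64_t u, int f) {
  int64_t v = static_cast<int64_t>(u); // two's complement
  return static_cast<double>(v) / std::pow(2.0, f);
}

// [[Rcpp::export(name = ".fsb_fp_encode")]]
NumericVector fsb_fp_encode(NumericVector x, int f) {
  R_xlen_t n = x.size();
  NumericVector out(2 * n);
  for (R_xlen_t i = 0; i < n; ++i) pack_word(&out[2 * i], fp_encode_one(x[i], f));
  return out;
}

// [[Rcpp::export(name = ".fsb_fp_decode")]]
NumericVector fsb_fp_decode(NumericVector packed, int f) {
  R_xlen_t n = packed.size() / 2;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = fp_decode_one(unpack_word(&packed[2 * i]), f);
  return out;
}

// split an encoded tensor into n_parties additive shares; the first
// n_parties - 1 shares are uniform ring elements from a seeded mt19937_64
// [[Rcpp::export(name = ".fsb_share_encoded")]]
List fsb_share_encoded(NumericVector packed, int n_parties, double seed) {
  if (n_parties < 2) stop("n_parties must be >= 2");
  R_xlen_t n = packed.size() / 2;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  List shares(n_parties);
  std::vector<uint64_t> acc(n, 0);
  for (int p = 0; p < n_parties - 1; ++p) {
    NumericVector s(2 * n);
    for (R_xlen_t i = 0; i < n; ++i) {
      uint64_t r = rng();
      acc[i] += r; // mod 2^64 by wraparound
      pack_word(&s[2 * i], r);
    }
    shares[p] = s;
  }
  NumericVector last(2 * n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = unpack_word(&packed[2 * i]);
    pack_word(&last[2 * i], v - acc[i]);
  }
  shares[n_parties - 1] = last;
  return shares;
}

// elementwise modular sum of two packed ring tensors
// [[Rcpp::export(name = ".fsb_ring_add")]]
NumericVector fsb_ring_add(NumericVector a, NumericVector b) {
  if (a.size() != b.size()) stop("ring tensors differ in length");
  R_xlen_t n2 = a.size();
  NumericVector out(n2);
  for (R_xlen_t i = 0; i < n2; i += 2) {
    pack_word(&out[i], unpack_word(&a[i]) + unpack_word(&b[i]));
  }
  return out;
}

// sign of the two's-complement value of each packed element: -1, 0, +1
// [[Rcpp::export(name = ".fsb_ring_sign")]]
IntegerVector fsb_ring_sign(NumericVector packed) {
  R_xlen_t n = packed.size() / 2;
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int64_t v = static_cast<int64_t>(unpack_word(&packed[2 * i]));
    out[i] = (v > 0) - (v < 0);
  }
  return out;
}

// modular negation, used to form share-space differences
// [[Rcpp::export(name = ".fsb_ring_neg")]]
NumericVector fsb_ring_neg(NumericVector a) {
  R_xlen_t n2 = a.size();
  NumericVector out(n2);
  for (R_xlen_t i = 0; i < n2; i += 2) {
    pack_word(&out[i], ~unpack_word(&a[i]) + 1ULL);
  }
  return out;
}
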