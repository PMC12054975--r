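#include "core.h"

#include <algorithm>
#include <cerrno>
#include <cmath>
#include <cstdlib>
#include <set>

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t getblock64(const uint8_t *p) {
  uint64_t v;
  std::memcpy(&v, p, 8);  // little-endian hosts; bytes reassembled explicitly below for BE safety
#if defined(__BYTE_ORDER__) && (__BYTE_ORDER__ == __ORDER_BIG_ENDIAN__)
  v = __builtin_bswap64(v);
#endif
  return v;
}

uint64_t murmur3_lo64(const void *data, size_t len, uint32_t seed) {
  const uint8_t *p = (const uint8_t *)data;
  const size_t nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (size_t i = 0; i < nblocks; ++i) {
    uint64_t k1 = getblock64(p + i * 16);
    uint64_t k2 = getblock64(p + i * 16 + 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729ULL;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5ULL;
  }

  const uint8_t *tail = p + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
    case 15: k2 ^= ((uint64_t)tail[14]) << 48; // fall through
    case 14: k2 ^= ((uint64_t)tail[13]) << 40; // fall through
    case 13: k2 ^= ((uint64_t)tail[12]) << 32; // fall through
    case 12: k2 ^= ((uint64_t)tail[11]) << 24; // fall through
    case 11: k2 ^= ((uint64_t)tail[10]) << 16; // fall through
    case 10: k2 ^= ((uint64_t)tail[9]) << 8;   // fall through
    case 9:  k2 ^= ((uint64_t)tail[8]) << 0;
             k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
             // fall through
    case 8:  k1 ^= ((uint64_t)tail[7]) << 56;  // fall through
    case 7:  k1 ^= ((uint64_t)tail[6]) << 48;  // fall through
    case 6:  k1 ^= ((uint64_t)tail[5]) << 40;  // fall through
    case 5:  k1 ^= ((uint64_t)tail[4]) << 32;  // fall through
    case 4:  k1 ^= ((uint64_t)tail[3]) << 24;  // fall through
    case 3:  k1 ^= ((uint64_t)tail[2]) << 16;  // fall through
    case 2:  k1 ^= ((uint64_t)tail[1]) << 8;   // fall through
    case 1:  k1 ^= ((uint64_t)tail[0]) << 0;
             k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= (uint64_t)len; h2 ^= (uint64_t)len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;  // h2 += h1 would complete the 128-bit digest; only h1 is kept
  return h1;
}

uint64_t str2u64(const char *s) {
  if (s == nullptr || *s == '\0')
    Rcpp::stop("empty string is not a valid unsigned 64-bit integer");
  uint64_t v = 0;
  for (const char *q = s; *q; ++q) {
    if (*q < '0' || *q > '9')
      Rcpp::stop("'%s' is not a valid unsigned 64-bit decimal integer", s);
    uint64_t d = (uint64_t)(*q - '0');
    if (v > (UINT64_MAX - d) / 10)
      Rcpp::stop("'%s' overflows an unsigned 64-bit integer", s);
    v = v * 10 + d;
  }
  return v;
}

std::vector<uint64_t> chr2u64(const Rcpp::CharacterVector &x) {
  std::vector<uint64_t> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = str2u64(CHAR(STRING_ELT(x, i)));
  return out;
}

Rcpp::CharacterVector u642chr(const std::vector<uint64_t> &v) {
  Rcpp::CharacterVector out(v.size());
  char buf[24];
  for (size_t i = 0; i < v.size(); ++i) {
    snprintf(buf, sizeof(buf), "%llu", (unsigned long long)v[i]);
    out[i] = buf;
  }
  return out;
}

static uint32_t as_seed32(double seed) {
  if (seed < 0 || seed != std::floor(seed) || seed > 4294967295.0)
    Rcpp::stop("hash seed must be an integer in [0, 2^32)");
  return (uint32_t)seed;
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_murmur64(Rcpp::CharacterVector data, double seed) {
  uint32_t s = as_seed32(seed);
  std::vector<uint64_t> out(data.size());
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    const char *p = CHAR(STRING_ELT(data, i));
    out[i] = murmur3_lo64(p, std::strlen(p), s);
  }
  return u642chr(out);
}

// Batch variant: processes items in fixed-width chunks (stand-in for the SIMD
// multi-lane layout); contractually bit-identical to the scalar map.
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_murmur64_batch(Rcpp::CharacterVector data, double seed) {
  uint32_t s = as_seed32(seed);
  const R_xlen_t n = data.size();
  const R_xlen_t lane = 8;
  std::vector<uint64_t> out(n);
  for (R_xlen_t base = 0; base < n; base += lane) {
    R_xlen_t width = std::min(lane, n - base);
    const char *ptrs[8];
    size_t lens[8];
    for (R_xlen_t j = 0; j < width; ++j) {
      ptrs[j] = CHAR(STRING_ELT(data, base + j));
      lens[j] = std::strlen(ptrs[j]);
    }
    for (R_xlen_t j = 0; j < width; ++j)
      out[base + j] = murmur3_lo64(ptrs[j], lens[j], s);
  }
  return u642chr(out);
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_wang_mix(Rcpp::CharacterVector x) {
  std::vector<uint64_t> v = chr2u64(x);
  for (auto &e : v) e = wang_mix64(e);
  return u642chr(v);
}

// n pseudo-random, pairwise-distinct 64-bit values from a seeded splitmix64
// stream (used for estimator calibration and test fixtures).
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_random_u64(int n, double seed) {
  if (n < 0) Rcpp::stop("n must be non-negative");
  uint64_t state = (uint64_t)seed;
  std::vector<uint64_t> out;
  out.reserve(n);
  std::set<uint64_t> seen;
  while ((int)out.size() < n) {
    uint64_t v = splitmix64(state);
    if (seen.insert(v).second) out.push_back(v);
  }
  return u642chr(out);
}

// [[Rcpp::export]]
bool cpp_u64_sorted_distinct(Rcpp::CharacterVector x) {
  std::vector<uint64_t> v = chr2u64(x);
  for (size_t i = 1; i < v.size(); ++i)
    if (v[i] <= v[i - 1]) return false;
  return true;
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_sort_u64(Rcpp::CharacterVector x, bool unique_) {
  std::vector<uint64_t> v = chr2u64(x);
  std::sort(v.begin(), v.end());
  if (unique_) v.erase(std::unique(v.begin(), v.end()), v.end());
  return u642chr(v);
}
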