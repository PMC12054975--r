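#ifndef GENOSKETCH_CORE_H
#define GENOSKETCH_CORE_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

// MurmurHash3 x64_128, lower 64 bits of the digest (h1).
uint64_t murmur3_lo64(const void *data, size_t len, uint32_t seed);

// Thomas Wang's 64-bit invertible integer mix.
static inline uint64_t wang_mix64(uint64_t key) {
  key = (~key) + (key << 21);
  key = key ^ (key >> 24);
  key = (key + (key << 3)) + (key << 8);
  key = key ^ (key >> 14);
  key = (key + (key << 2)) + (key << 4);
  key = key ^ (key >> 28);
  key = key + (key << 31);
  return key;
}

// splitmix64: the dictionary / fixture PRNG. State advances by the golden
// gamma; output is a finalized mix of the state.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// ---- uint64 <-> decimal-string plumbing (R has no native 64-bit ints) ----

uint64_t str2u64(const char *s);
std::vector<uint64_t> chr2u64(const Rcpp::CharacterVector &x);
Rcpp::CharacterVector u642chr(const std::vector<uint64_t> &v);

// ---- nucleotide tables ----

// 2-bit base codes: A=0, C=1, G=2, T=3 (case-insensitive); N/n = -2;
// anything else = -1 (invalid).
extern const int8_t *const BASE_CODE;
extern const char CODE_BASE[4];
// Complement lookup (uppercasing folded in); 0 marks an invalid character.
extern const char *const COMP_CHAR;

// Decode a 2-bit packed k-mer (leftmost base in the most significant bits)
// into `out` (must hold k chars).
static inline void decode_kmer(uint64_t code, int k, char *out) {
  for (int i = k - 1; i >= 0; --i) {
    out[i] = CODE_BASE[code & 3ULL];
    code >>= 2;
  }
}

// Scan a sequence, calling fn(pos, fwd_code, canon_code) for every window of
// length k made only of ACGT (case-insensitive). Windows containing N are
// skipped; any other character aborts with an error naming its position.
template <typename F>
void for_each_kmer(const std::string &seq, int k, F fn) {
  const size_t n = seq.size();
  if (k < 1 || k > 32) Rcpp::stop("k must be in [1, 32], got %d", k);
  if (n < (size_t)k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0;  // length of the current run of ACGT bases
  for (size_t i = 0; i < n; ++i) {
    int8_t b = BASE_CODE[(uint8_t)seq[i]];
    if (b == -1)
      Rcpp::stop("invalid nucleotide '%c' at position %d (expected A/C/G/T/N)",
                 seq[i], (int)(i + 1));
    if (b == -2) { valid = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid >= k) {
      uint64_t canon = fwd < rc ? fwd : rc;
      fn(i + 1 - (size_t)k, fwd, canon);
    }
  }
}

#endif
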