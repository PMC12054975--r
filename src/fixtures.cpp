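#include "core.h"

// Uniform i.i.d. ACGT genome from a seeded splitmix64 stream (independent of
// R's RNG so fixtures are reproducible across platforms and sessions).
// [[Rcpp::export]]
std::string cpp_random_genome(double length, double seed) {
  if (length < 0) Rcpp::stop("length must be non-negative");
  const size_t n = (size_t)length;
  uint64_t state = (uint64_t)seed;
  std::string out(n, 'A');
  for (size_t i = 0; i < n; ++i)
    out[i] = CODE_BASE[splitmix64(state) >> 62];  // top 2 bits: uniform base
  return out;
}

// Independent per-base substitution at the given rate; a substituted base is
// always changed to one of the three other bases. Non-ACGT characters are
// left untouched.
// [[Rcpp::export]]
std::string cpp_mutate(std::string seq, double rate, double seed) {
  if (rate < 0 || rate > 1) Rcpp::stop("substitution rate must be in [0, 1]");
  uint64_t state = (uint64_t)seed;
  const double inv = 1.0 / 18446744073709551616.0;  // 2^-64
  for (size_t i = 0; i < seq.size(); ++i) {
    double u = (double)splitmix64(state) * inv;
    int8_t b = BASE_CODE[(uint8_t)seq[i]];
    if (u < rate && b >= 0) {
      int nb = (b + 1 + (int)(splitmix64(state) % 3)) & 3;
      seq[i] = CODE_BASE[nb];
    }
  }
  return seq;
}

// n random edits applied sequentially; each edit is a substitution, an
// insertion, or a deletion with equal probability, at a uniform position.
// Deletions are skipped once the sequence would become empty.
// [[Rcpp::export]]
std::string cpp_random_edits(std::string seq, int n_edits, double seed) {
  if (n_edits < 0) Rcpp::stop("n_edits must be non-negative");
  uint64_t state = (uint64_t)seed;
  for (int e = 0; e < n_edits; ++e) {
    uint64_t op = splitmix64(state) % 3;
    if (seq.empty()) op = 1;  // only insertion is possible
    size_t p = seq.empty() ? 0 : (size_t)(splitmix64(state) % seq.size());
    if (op == 0) {  // substitution to a different base
      int8_t b = BASE_CODE[(uint8_t)seq[p]];
      if (b < 0) b = 0;
      seq[p] = CODE_BASE[(b + 1 + (int)(splitmix64(state) % 3)) & 3];
    } else if (op == 1) {  // insertion
      size_t at = (size_t)(splitmix64(state) % (seq.size() + 1));
      seq.insert(seq.begin() + at, CODE_BASE[splitmix64(state) >> 62]);
    } else {  // deletion
      if (seq.size() > 1) seq.erase(seq.begin() + p);
    }
  }
  return seq;
}
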