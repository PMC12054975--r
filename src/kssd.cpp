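#include "core.h"

#include <algorithm>

// Seeded Fisher-Yates shuffle of the substring code space [0, 4^L) driven by
// splitmix64. perm[c] is the shuffled rank of code c; codes whose rank falls
// below 4^(L-d) are the "valid" 1/4^d fraction used for sketching.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_kssd_dictionary(int half_k, int drlevel, double seed) {
  if (half_k < 1 || half_k > 10)
    Rcpp::stop("half_k must be in [1, 10] (the 4^L rank array must fit memory)");
  if (drlevel < 0 || drlevel > half_k)
    Rcpp::stop("drlevel must be in [0, half_k]: cannot reduce below one code");
  const int64_t n = (int64_t)1 << (2 * half_k);
  Rcpp::IntegerVector perm((R_xlen_t)n);
  for (int64_t i = 0; i < n; ++i) perm[i] = (int)i;
  uint64_t state = (uint64_t)seed;
  for (int64_t i = n - 1; i > 0; --i) {
    int64_t j = (int64_t)(splitmix64(state) % (uint64_t)(i + 1));
    std::swap(perm[i], perm[j]);
  }
  return perm;
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_perm_checksum(Rcpp::IntegerVector perm) {
  std::vector<uint64_t> v(1);
  v[0] = murmur3_lo64(INTEGER(perm), (size_t)perm.size() * sizeof(int), 0u);
  return u642chr(v);
}

static inline uint64_t central_code(uint64_t kmer_code, int k, int half_k) {
  const int start = (k - half_k) / 2;  // leftmost base of the central window
  const int shift = 2 * (k - start - half_k);
  const uint64_t mask = ((uint64_t)1 << (2 * half_k)) - 1;
  return (kmer_code >> shift) & mask;
}

// Shared scan used by both the full-permutation and map-dictionary paths;
// `is_valid` decides membership of the central substring code.
template <typename V>
static Rcpp::CharacterVector kssd_scan(Rcpp::CharacterVector cur, const std::string &seq,
                                       int k, int half_k, bool canonical, V is_valid) {
  if (k < half_k) Rcpp::stop("k (%d) must be >= half_k (%d)", k, half_k);
  std::vector<uint64_t> codes = chr2u64(cur);
  for_each_kmer(seq, k, [&](size_t, uint64_t fwd, uint64_t canon) {
    uint64_t kc = canonical ? canon : fwd;
    if (is_valid(central_code(kc, k, half_k))) codes.push_back(kc);
  });
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  return u642chr(codes);
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_kssd_update(Rcpp::CharacterVector cur, std::string seq,
                                      int k, int half_k, int drlevel,
                                      Rcpp::IntegerVector perm, bool canonical) {
  const int64_t n_valid = (int64_t)1 << (2 * (half_k - drlevel));
  const int *p = INTEGER(perm);
  if ((int64_t)perm.size() != ((int64_t)1 << (2 * half_k)))
    Rcpp::stop("perm length does not match 4^half_k");
  return kssd_scan(cur, seq, k, half_k, canonical,
                   [&](uint64_t c) { return (int64_t)p[c] < n_valid; });
}

// Map-dictionary path: membership through the compact sorted table of valid
// codes only; must be bit-identical to the full-permutation path.
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_kssd_update_map(Rcpp::CharacterVector cur, std::string seq,
                                          int k, int half_k,
                                          Rcpp::NumericVector valid_codes,
                                          bool canonical) {
  std::vector<uint64_t> valid(valid_codes.size());
  for (R_xlen_t i = 0; i < valid_codes.size(); ++i)
    valid[i] = (uint64_t)valid_codes[i];
  std::sort(valid.begin(), valid.end());
  return kssd_scan(cur, seq, k, half_k, canonical, [&](uint64_t c) {
    return std::binary_search(valid.begin(), valid.end(), c);
  });
}

// Exact Jaccard of the canonical k-mer code sets of two sequences
// (hash-free brute-force oracle).
// [[Rcpp::export]]
Rcpp::List cpp_exact_jaccard(std::string a, std::string b, int k) {
  std::vector<uint64_t> sa, sb;
  for_each_kmer(a, k, [&](size_t, uint64_t, uint64_t canon) { sa.push_back(canon); });
  for_each_kmer(b, k, [&](size_t, uint64_t, uint64_t canon) { sb.push_back(canon); });
  std::sort(sa.begin(), sa.end()); sa.erase(std::unique(sa.begin(), sa.end()), sa.end());
  std::sort(sb.begin(), sb.end()); sb.erase(std::unique(sb.begin(), sb.end()), sb.end());
  size_t i = 0, j = 0, inter = 0;
  while (i < sa.size() && j < sb.size()) {
    if (sa[i] == sb[j]) { ++inter; ++i; ++j; }
    else if (sa[i] < sb[j]) ++i;
    else ++j;
  }
  size_t uni = sa.size() + sb.size() - inter;
  double jac = uni == 0 ? 1.0 : (double)inter / (double)uni;
  return Rcpp::List::create(Rcpp::Named("jaccard") = jac,
                            Rcpp::Named("shared") = (double)inter,
                            Rcpp::Named("denom") = (double)uni);
}
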