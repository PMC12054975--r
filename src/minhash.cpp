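#include "core.h"

#include <algorithm>

// Hash of a canonical k-mer: MurmurHash3 x64_128 (lower 64) over the ASCII
// string of the k-mer, so sketches are comparable across encodings and k.
static uint64_t hash_code(uint64_t code, int k, uint32_t seed, char *buf) {
  decode_kmer(code, k, buf);
  return murmur3_lo64(buf, (size_t)k, seed);
}

// Fold one sequence into a bottom-s sketch held as a sorted distinct vector.
// Returns the updated hash list plus the number of k-mer windows consumed.
// [[Rcpp::export]]
Rcpp::List cpp_minhash_update(Rcpp::CharacterVector cur, std::string seq,
                              int k, int s, double seed) {
  if (s < 1) Rcpp::stop("sketch size s must be >= 1");
  uint32_t sd = (uint32_t)seed;
  std::vector<uint64_t> pool = chr2u64(cur);
  std::vector<char> buf(k, 0);
  long long nk = 0;
  // current admission threshold: with a full sketch only hashes below the
  // retained maximum can enter
  for_each_kmer(seq, k, [&](size_t, uint64_t, uint64_t canon) {
    ++nk;
    pool.push_back(hash_code(canon, k, sd, buf.data()));
  });
  std::sort(pool.begin(), pool.end());
  pool.erase(std::unique(pool.begin(), pool.end()), pool.end());
  if ((int)pool.size() > s) pool.resize(s);
  return Rcpp::List::create(Rcpp::Named("hashes") = u642chr(pool),
                            Rcpp::Named("n_kmers") = (double)nk);
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_bottom_union(Rcpp::CharacterVector a,
                                       Rcpp::CharacterVector b, int s) {
  std::vector<uint64_t> va = chr2u64(a), vb = chr2u64(b), u;
  u.reserve(va.size() + vb.size());
  std::set_union(va.begin(), va.end(), vb.begin(), vb.end(), std::back_inserter(u));
  if ((int)u.size() > s) u.resize(s);
  return u642chr(u);
}

// Mash-style sketch Jaccard: among the s' = min(s, |union|) smallest values
// of the union of the two retained lists, count those present in both.
// [[Rcpp::export]]
Rcpp::List cpp_minhash_jaccard(Rcpp::CharacterVector a, Rcpp::CharacterVector b,
                               int s) {
  std::vector<uint64_t> va = chr2u64(a), vb = chr2u64(b);
  size_t i = 0, j = 0, uni = 0, shared_capped = 0;
  const size_t cap = (size_t)s;
  while (i < va.size() || j < vb.size()) {
    bool both;
    if (i < va.size() && j < vb.size() && va[i] == vb[j]) {
      both = true; ++i; ++j;
    } else if (j >= vb.size() || (i < va.size() && va[i] < vb[j])) {
      both = false; ++i;
    } else {
      both = false; ++j;
    }
    if (both && uni < cap) ++shared_capped;
    ++uni;
  }
  size_t denom = std::min(cap, uni);
  return Rcpp::List::create(Rcpp::Named("shared") = (int)shared_capped,
                            Rcpp::Named("denom") = (int)denom);
}

// All distinct canonical k-mer hashes of a sequence, sorted ascending
// (brute-force support for oracles and for HLL exact-count comparisons).
// [[Rcpp::export]]
Rcpp::CharacterVector cpp_all_kmer_hashes(std::string seq, int k, double seed,
                                          bool canonical) {
  uint32_t sd = (uint32_t)seed;
  std::vector<char> buf(k, 0);
  std::vector<uint64_t> v;
  for_each_kmer(seq, k, [&](size_t, uint64_t fwd, uint64_t canon) {
    v.push_back(hash_code(canonical ? canon : fwd, k, sd, buf.data()));
  });
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return u642chr(v);
}
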